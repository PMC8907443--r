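# First-order (statistical) intensity features over the ROI.

#' First-order features of ROI intensities
#'
#' Moments use the population (1/n) convention. Skewness and kurtosis of a
#' constant ROI are undefined by convention and returned as `NA`; the
#' coefficient of variation and quartile dispersion are `NA` when their
#' denominator is (near) zero. Uniformity and entropy are computed on the
#' discretized grey levels.
#'
#' @param volume 3D numeric array (typically normalized).
#' @param mask 3D binary array, nonempty.
#' @param disc A [discretization_params()].
#' @param voxel_volume Voxel volume in mm^3 (for total energy).
#' @return Named numeric vector over the 22 first-order catalog features.
#' @export
firstorder_features <- function(volume, mask, disc = discretization_params(),
                                voxel_volume = 1) {
  x <- volume[mask != 0]
  n <- length(x)
  if (n == 0) stop("empty mask")
  mu <- mean(x)
  m2 <- mean((x - mu)^2)
  m3 <- mean((x - mu)^3)
  m4 <- mean((x - mu)^4)
  skew <- if (m2 > 0) m3 / m2^1.5 else NA_real_
  kurt <- if (m2 > 0) m4 / m2^2 else NA_real_
  qs <- unname(quantile(x, c(0.1, 0.25, 0.5, 0.75, 0.9), type = 7))
  covv <- if (abs(mu) > 1e-12) sqrt(m2) / mu else NA_real_
  qsum <- qs[4] + qs[2]
  qcod <- if (abs(qsum) > 1e-12) (qs[4] - qs[2]) / qsum else NA_real_

  dz <- discretize_values(x, disc)
  p <- tabulate(dz$levels, nbins = dz$n_levels) / n
  p <- p[p > 0]
  uniformity <- sum(p^2)
  entropy <- -sum(p * log2(p))

  out <- c(mu, m2, sqrt(m2), skew, kurt, min(x), max(x), diff(range(x)),
           qs[1], qs[2], qs[3], qs[4], qs[5], qs[4] - qs[2],
           sum(x^2), voxel_volume * sum(x^2), sqrt(mean(x^2)),
           mean(abs(x - mu)), covv, qcod, uniformity, entropy)
  names(out) <- FO_NAMES
  out
}
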