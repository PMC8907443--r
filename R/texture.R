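# Textural features: grey-level co-occurrence (GLCM) and run-length
# (GLRLM) families, computed over the 13 unique 3D directions and averaged
# (IBSI "average over directions" aggregation). Heavy counting is compiled.

# Discretized grey-level array cropped to the ROI bounding box: 0 outside
# the ROI, 1..ng inside. (Texture features are translation-invariant, so
# cropping only saves counting time.)
levels_array <- function(volume, mask, disc) {
  inroi <- mask != 0
  dz <- discretize_values(volume[inroi], disc)
  lv <- array(0L, dim(mask))
  lv[inroi] <- dz$levels
  d <- dim(lv)
  idx <- which(inroi) - 1L
  ix <- idx %% d[1]
  iy <- (idx %/% d[1]) %% d[2]
  iz <- idx %/% (d[1] * d[2])
  lv <- lv[(min(ix) + 1L):(max(ix) + 1L),
           (min(iy) + 1L):(max(iy) + 1L),
           (min(iz) + 1L):(max(iz) + 1L), drop = FALSE]
  list(levels = lv, n_levels = dz$n_levels)
}

# Normalized symmetric co-occurrence matrix for a single direction offset;
# exposed for oracle tests.
glcm_matrix <- function(levels, offset, n_levels) {
  counts <- cpp_glcm_counts(as.integer(levels), dim(levels),
                            matrix(as.integer(offset), 1, 3), n_levels)
  m <- matrix(counts[, , 1], n_levels, n_levels)
  s <- sum(m)
  if (s > 0) m / s else m
}

# Cached index grids and weight vectors per matrix size (all GLCMs of one
# extraction share ng).
.glcm_idx_cache <- new.env(parent = emptyenv())
glcm_idx <- function(ng) {
  key <- as.character(ng)
  cached <- .glcm_idx_cache[[key]]
  if (!is.null(cached)) return(cached)
  i <- matrix(rep(seq_len(ng), ng), ng)
  j <- t(i)
  iv <- as.vector(i)
  jv <- as.vector(j)
  absd <- abs(iv - jv)
  s <- iv + jv
  out <- list(
    i = i, j = j, iv = iv, jv = jv,
    dif = absd + 1L, ssum = s - 1L,
    w_ij = iv * jv, w_contrast = (iv - jv)^2, w_absd = absd,
    w_i2 = iv^2,
    w_invd = 1 / (1 + absd), w_idm = 1 / (1 + (iv - jv)^2),
    w_idmn = 1 / (1 + (absd / ng)^2), w_idn = 1 / (1 + absd / ng),
    w_invvar = ifelse(absd > 0, 1 / absd^2, 0),
    s1 = s, s2 = s^2, s3 = s^3, s4 = s^4,
    dvals = 0:(ng - 1), svals = 2:(2 * ng))
  .glcm_idx_cache[[key]] <- out
  out
}

# xlog2x with the 0*log(0) = 0 convention.
xlog2 <- function(p) {
  out <- p * 0
  pos <- p > 0
  out[pos] <- p[pos] * log2(p[pos])
  out
}

# All-directions GLCM features: P is an (ng^2 x n_dirs) matrix of
# normalized symmetric co-occurrence probabilities, one column per
# direction. Returns a 25 x n_dirs matrix (same rows as glcm_stats, which
# stays as the independent single-matrix reference used by the tests).
glcm_stats_multi <- function(P, ng) {
  ix <- glcm_idx(ng)
  nd <- ncol(P)
  mu <- colSums(P * ix$iv)                    # == joint_average (symmetric)
  autoc <- colSums(P * ix$w_ij)
  sigma2 <- colSums(P * ix$w_i2) - mu^2
  corr <- ifelse(sigma2 > 1e-12, (autoc - mu^2) / sigma2, NA_real_)

  S1 <- colSums(P * ix$s1)
  S2 <- colSums(P * ix$s2)
  S3 <- colSums(P * ix$s3)
  S4 <- colSums(P * ix$s4)
  ct <- S2 - 4 * mu^2
  cs <- S3 - 6 * mu * S2 + 16 * mu^3
  cp <- S4 - 8 * mu * S3 + 24 * mu^2 * S2 - 48 * mu^4

  pd <- rowsum(P, ix$dif, reorder = TRUE)     # ng x nd, groups 0..ng-1
  ps <- rowsum(P, ix$ssum, reorder = TRUE)    # (2ng-1) x nd, groups 2..2ng
  da <- colSums(pd * ix$dvals)
  dvar <- colSums(pd * ix$dvals^2) - da^2
  dent <- -colSums(xlog2(pd))
  sa <- colSums(ps * ix$svals)
  svar <- colSums(ps * ix$svals^2) - sa^2
  sent <- -colSums(xlog2(ps))

  HXY <- -colSums(xlog2(P))
  px <- rowsum(P, ix$iv, reorder = TRUE)      # ng x nd marginal
  HX <- -colSums(xlog2(px))
  lpx <- px * 0
  lpx[px > 0] <- log2(px[px > 0])
  lcell <- lpx[ix$iv, , drop = FALSE] + lpx[ix$jv, , drop = FALSE]
  HXY1 <- -colSums(P * lcell)
  pxy <- px[ix$iv, , drop = FALSE] * px[ix$jv, , drop = FALSE]
  HXY2 <- -colSums(pxy * lcell)
  imc1 <- ifelse(HX > 0, (HXY - HXY1) / HX, NA_real_)
  imc2 <- sqrt(pmax(0, 1 - exp(-2 * (HXY2 - HXY))))

  rbind(
    autocorrelation = autoc, joint_average = mu,
    cluster_prominence = cp, cluster_shade = cs, cluster_tendency = ct,
    contrast = colSums(P * ix$w_contrast), correlation = corr,
    difference_average = da, difference_entropy = dent,
    difference_variance = dvar, dissimilarity = colSums(P * ix$w_absd),
    joint_energy = colSums(P^2), joint_entropy = HXY,
    inverse_difference = colSums(P * ix$w_invd),
    idm = colSums(P * ix$w_idm), idmn = colSums(P * ix$w_idmn),
    idn = colSums(P * ix$w_idn), imc1 = imc1, imc2 = imc2,
    inverse_variance = colSums(P * ix$w_invvar),
    max_probability = apply(P, 2, max),
    sum_average = sa, sum_entropy = sent, sum_variance = svar,
    joint_variance = sigma2)
}

# Feature vector of one normalized symmetric GLCM.
glcm_stats <- function(P) {
  ng <- nrow(P)
  ix <- glcm_idx(ng)
  i <- ix$i
  j <- ix$j
  px <- rowSums(P)               # symmetric: px == py
  mu <- sum(seq_len(ng) * px)
  sig2 <- sum((seq_len(ng) - mu)^2 * px)
  pos <- P > 0

  # difference and sum marginals via grouped sums
  dvals <- 0:(ng - 1)
  pd <- numeric(ng)
  rs <- rowsum(as.vector(P), ix$dif)
  pd[as.integer(rownames(rs))] <- rs
  svals <- 2:(2 * ng)
  ps <- numeric(2 * ng - 1)
  rs <- rowsum(as.vector(P), ix$ssum)
  ps[as.integer(rownames(rs))] <- rs

  da <- sum(dvals * pd)
  se_p <- ps[ps > 0]
  de_p <- pd[pd > 0]
  sa <- sum(svals * ps)

  HXY <- -sum(P[pos] * log2(P[pos]))
  HX <- -sum(px[px > 0] * log2(px[px > 0]))
  pxy <- outer(px, px)
  HXY1 <- -sum(P[pos & pxy > 0] * log2(pxy[pos & pxy > 0]))
  HXY2 <- -sum(pxy[pxy > 0] * log2(pxy[pxy > 0]))
  imc1 <- if (HX > 0) (HXY - HXY1) / HX else NA_real_
  imc2 <- sqrt(pmax(0, 1 - exp(-2 * (HXY2 - HXY))))

  corr <- if (sig2 > 1e-12) (sum(i * j * P) - mu^2) / sig2 else NA_real_
  offdiag <- i != j

  out <- c(
    autocorrelation = sum(i * j * P),
    joint_average = mu,
    cluster_prominence = sum((i + j - 2 * mu)^4 * P),
    cluster_shade = sum((i + j - 2 * mu)^3 * P),
    cluster_tendency = sum((i + j - 2 * mu)^2 * P),
    contrast = sum((i - j)^2 * P),
    correlation = corr,
    difference_average = da,
    difference_entropy = -sum(de_p * log2(de_p)),
    difference_variance = sum((dvals - da)^2 * pd),
    dissimilarity = sum(abs(i - j) * P),
    joint_energy = sum(P^2),
    joint_entropy = HXY,
    inverse_difference = sum(P / (1 + abs(i - j))),
    idm = sum(P / (1 + (i - j)^2)),
    idmn = sum(P / (1 + (abs(i - j) / ng)^2)),
    idn = sum(P / (1 + abs(i - j) / ng)),
    imc1 = imc1,
    imc2 = imc2,
    inverse_variance = sum(P[offdiag] / (i[offdiag] - j[offdiag])^2),
    max_probability = max(P),
    sum_average = sa,
    sum_entropy = -sum(se_p * log2(se_p)),
    sum_variance = sum((svals - sa)^2 * ps),
    joint_variance = sum((i - mu)^2 * P))
  out
}

#' Grey-level co-occurrence features
#'
#' Symmetric co-occurrence matrices over the 13 unique 3D directions
#' (Chebyshev neighbours) at each requested distance, restricted to voxel
#' pairs inside the ROI, normalized to probabilities; 25 features per
#' distance, averaged over directions (directions with no in-ROI pair are
#' dropped from the average). Correlation and the information measures of
#' a single-level ROI are undefined by convention and returned as `NA`.
#'
#' @param volume 3D numeric array.
#' @param mask 3D binary array with at least 2 ROI voxels.
#' @param disc A [discretization_params()].
#' @param distances Integer distances (default `c(1, 2)`).
#' @return Named numeric vector (`glcm_<feature>_d<distance>`).
#' @export
glcm_features <- function(volume, mask, disc = discretization_params(),
                          distances = c(1L, 2L)) {
  if (sum(mask != 0) < 2) stop("GLCM needs at least 2 ROI voxels")
  la <- levels_array(volume, mask, disc)
  ng <- la$n_levels
  out <- numeric(0)
  for (dst in distances) {
    counts <- cpp_glcm_counts(la$levels, dim(la$levels),
                              DIRECTIONS_13 * as.integer(dst), ng)
    M <- matrix(counts, ng * ng, nrow(DIRECTIONS_13))
    tot <- colSums(M)
    keep <- tot > 0   # directions with no in-ROI pair drop from the average
    if (any(keep)) {
      P <- sweep(M[, keep, drop = FALSE], 2, tot[keep], `/`)
      vals <- glcm_stats_multi(P, ng)
      avg <- rowMeans(vals)
    } else {
      avg <- rep(NA_real_, length(GLCM_BASE_NAMES))
    }
    names(avg) <- paste0("glcm_", GLCM_BASE_NAMES, "_d", dst)
    out <- c(out, avg)
  }
  out
}

#' Grey-level run-length features
#'
#' Run-length matrices along the 13 unique 3D directions at distance 1,
#' 10 features per direction, averaged over directions.
#'
#' @inheritParams glcm_features
#' @return Named numeric vector over the 10 run-length catalog features.
#' @export
glrlm_features <- function(volume, mask, disc = discretization_params()) {
  nvox <- sum(mask != 0)
  if (nvox < 1) stop("empty mask")
  la <- levels_array(volume, mask, disc)
  maxlen <- max(dim(mask))
  counts <- cpp_glrlm_counts(la$levels, dim(la$levels), DIRECTIONS_13,
                             la$n_levels, maxlen)
  g <- seq_len(la$n_levels)
  l <- seq_len(maxlen)
  vals <- matrix(NA_real_, length(GLRLM_NAMES), nrow(DIRECTIONS_13))
  for (d in seq_len(nrow(DIRECTIONS_13))) {
    r <- counts[, , d, drop = FALSE]
    dim(r) <- c(la$n_levels, maxlen)
    ns <- sum(r)
    if (ns == 0) next
    rg <- rowSums(r)
    rl <- colSums(r)
    gl2 <- outer(g^2, l^2)
    vals[, d] <- c(
      sum(sweep(r, 2, l^2, `/`)) / ns,
      sum(sweep(r, 2, l^2, `*`)) / ns,
      sum(rg^2) / ns,
      sum(rl^2) / ns,
      ns / nvox,
      sum(r / g^2) / ns,
      sum(r * g^2) / ns,
      sum(r / gl2) / ns,
      sum(sweep(r * g^2, 2, l^2, `/`)) / ns,
      sum(r * gl2) / ns)
  }
  ok <- colSums(!is.na(vals)) > 0
  avg <- if (any(ok)) rowMeans(vals[, ok, drop = FALSE])
         else rep(NA_real_, length(GLRLM_NAMES))
  names(avg) <- GLRLM_NAMES
  avg
}
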