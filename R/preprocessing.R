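#' Intensity normalization parameters
#'
#' The MR signal scale of low-field TrueFISP images is arbitrary, so
#' intensities are standardized before statistical/textural feature
#' extraction. The default is a z-score over the whole volume; the
#' reference region can instead be the ROI dilated by one voxel, and the
#' standardized values can be clipped symmetrically.
#'
#' @param method `"zscore"` or `"none"` (identity).
#' @param reference_region `"whole_volume"` or `"roi_dilated"`.
#' @param clip_sd Optional positive clip bound in SD units.
#' @return Object of class `normalization_params`.
#' @export
normalization_params <- function(method = c("zscore", "none"),
                                 reference_region = c("whole_volume",
                                                      "roi_dilated"),
                                 clip_sd = NULL) {
  method <- match.arg(method)
  reference_region <- match.arg(reference_region)
  if (!is.null(clip_sd) && clip_sd <= 0)
    stop("clip_sd must be > 0 when given")
  structure(list(method = method, reference_region = reference_region,
                 clip_sd = clip_sd),
            class = "normalization_params")
}

# Binary dilation of a 3D mask by one voxel (6-connectivity), used for the
# roi_dilated reference region.
dilate_mask1 <- function(mask) {
  d <- dim(mask)
  out <- mask
  shift <- function(m, ax, by) {
    idx <- lapply(d, seq_len)
    src <- idx
    src[[ax]] <- clamp(idx[[ax]] - by, 1L, d[ax])
    m[src[[1]], src[[2]], src[[3]]]
  }
  for (ax in 1:3) for (by in c(-1L, 1L)) out <- out | shift(mask, ax, by)
  out
}

#' Normalize an MR volume
#'
#' @param volume 3D numeric array with finite values.
#' @param params A [normalization_params()].
#' @param mask Optional binary ROI mask, required when
#'   `reference_region = "roi_dilated"`.
#' @return Normalized 3D array of the same shape.
#' @export
normalize_volume <- function(volume, params = normalization_params(),
                             mask = NULL) {
  stopifnot(inherits(params, "normalization_params"))
  if (!all(is.finite(volume))) stop("volume contains non-finite values")
  if (params$method == "none") return(volume)
  ref <- if (params$reference_region == "whole_volume") {
    as.vector(volume)
  } else {
    if (is.null(mask)) stop("roi_dilated reference requires a mask")
    volume[dilate_mask1(mask != 0)]
  }
  if (!length(ref)) stop("empty reference region")
  mu <- mean(ref)
  sigma <- sd(ref)
  if (!is.finite(sigma) || sigma == 0)
    stop("constant reference region: sd is zero, cannot z-score")
  out <- (volume - mu) / sigma
  if (!is.null(params$clip_sd))
    out <- clamp(out, -params$clip_sd, params$clip_sd)
  out
}
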