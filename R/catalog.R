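# Feature catalog and grey-level discretization.

#' Discretization parameters for texture / histogram features
#'
#' @param strategy `"fixed_bin_count"` (default) or `"fixed_bin_size"`.
#' @param n_bins Number of grey levels for fixed_bin_count (>= 2;
#'   default 32, robust to the z-scored intensity scale).
#' @param bin_width Bin width for fixed_bin_size (> 0).
#' @param range_policy `"roi_min_max"` (default) or `"fixed_bounds"` with
#'   `bounds = c(lo, hi)`.
#' @param bounds Intensity bounds for the fixed_bounds policy.
#' @return Object of class `discretization_params`.
#' @export
discretization_params <- function(strategy = c("fixed_bin_count",
                                               "fixed_bin_size"),
                                  n_bins = 32L, bin_width = NULL,
                                  range_policy = c("roi_min_max",
                                                   "fixed_bounds"),
                                  bounds = NULL) {
  strategy <- match.arg(strategy)
  range_policy <- match.arg(range_policy)
  if (strategy == "fixed_bin_count" && n_bins < 2)
    stop("n_bins must be >= 2")
  if (strategy == "fixed_bin_size" && (is.null(bin_width) || bin_width <= 0))
    stop("bin_width must be > 0 for fixed_bin_size")
  if (range_policy == "fixed_bounds" &&
      (is.null(bounds) || length(bounds) != 2 || diff(bounds) <= 0))
    stop("fixed_bounds needs bounds = c(lo, hi) with hi > lo")
  structure(list(strategy = strategy, n_bins = as.integer(n_bins),
                 bin_width = bin_width, range_policy = range_policy,
                 bounds = bounds),
            class = "discretization_params")
}

#' Discretize ROI intensities to integer grey levels
#'
#' @param values Numeric vector of ROI intensities.
#' @param disc A [discretization_params()].
#' @return List with `levels` (integers 1..n_levels; a constant ROI maps to
#'   a single level) and `n_levels`.
#' @export
discretize_values <- function(values, disc = discretization_params()) {
  stopifnot(inherits(disc, "discretization_params"))
  rng <- if (disc$range_policy == "roi_min_max") range(values) else disc$bounds
  if (disc$strategy == "fixed_bin_count") {
    nb <- disc$n_bins
    if (rng[2] <= rng[1]) return(list(levels = rep(1L, length(values)),
                                      n_levels = 1L))
    lv <- pmin(nb, floor(nb * (values - rng[1]) / (rng[2] - rng[1])) + 1L)
    lv <- pmax(1L, as.integer(lv))
    list(levels = lv, n_levels = nb)
  } else {
    lv <- as.integer(floor((values - rng[1]) / disc$bin_width)) + 1L
    lv <- pmax(1L, lv)
    list(levels = lv, n_levels = max(lv))
  }
}

MORPH_NAMES <- paste0("morph_", c(
  "volume", "surface_area", "av_ratio", "sphericity", "compactness1",
  "compactness2", "spherical_disproportion", "equivalent_diameter",
  "max_diameter_3d", "major_axis", "minor_axis", "least_axis",
  "elongation", "flatness", "bbox_extent"))

FO_NAMES <- paste0("fo_", c(
  "mean", "variance", "sd", "skewness", "kurtosis", "min", "max", "range",
  "p10", "p25", "median", "p75", "p90", "iqr", "energy", "total_energy",
  "rms", "mad", "cov", "qcod", "uniformity", "entropy"))

GLCM_BASE_NAMES <- c(
  "autocorrelation", "joint_average", "cluster_prominence", "cluster_shade",
  "cluster_tendency", "contrast", "correlation", "difference_average",
  "difference_entropy", "difference_variance", "dissimilarity",
  "joint_energy", "joint_entropy", "inverse_difference", "idm", "idmn",
  "idn", "imc1", "imc2", "inverse_variance", "max_probability",
  "sum_average", "sum_entropy", "sum_variance", "joint_variance")

GLRLM_NAMES <- paste0("glrlm_", c(
  "sre", "lre", "gln", "rln", "rp", "lglre", "hglre", "srlgle", "srhgle",
  "lrhgle"))

# Features whose sign can legitimately cross zero; their deltas (ratios to
# simulation) are numerically valid but unstable, and are tagged as such.
RATIO_UNSTABLE <- c(
  "fo_mean", "fo_min", "fo_max", "fo_median", "fo_p10", "fo_p25", "fo_p75",
  "fo_p90", "fo_skewness", "fo_cov", "fo_qcod",
  paste0("glcm_cluster_shade_d", rep(1:2, each = 1)),
  paste0("glcm_imc1_d", 1:2), paste0("glcm_correlation_d", 1:2))

#' The default 97-feature catalog
#'
#' 15 morphological + 22 first-order + 50 grey-level co-occurrence (25
#' features at Chebyshev distances 1 and 2, averaged over the 13 unique 3D
#' directions) + 10 run-length features. Over 6 timepoints this yields the
#' 582 basal / 485 delta variable accounting of the default analysis.
#'
#' @param glcm_distances Integer co-occurrence distances (default `c(1, 2)`).
#' @return Data frame of class `feature_catalog` with columns `name`,
#'   `family`, `params`.
#' @export
feature_catalog <- function(glcm_distances = c(1L, 2L)) {
  glcm_names <- as.vector(vapply(glcm_distances, function(d)
    paste0("glcm_", GLCM_BASE_NAMES, "_d", d),
    character(length(GLCM_BASE_NAMES))))
  cat <- rbind(
    data.frame(name = MORPH_NAMES, family = "morphological",
               params = "surface=mesh", stringsAsFactors = FALSE),
    data.frame(name = FO_NAMES, family = "statistical",
               params = "discretization=catalog", stringsAsFactors = FALSE),
    data.frame(name = glcm_names, family = "textural",
               params = paste0("distance=",
                               rep(glcm_distances,
                                   each = length(GLCM_BASE_NAMES)),
                               ";aggregation=average_over_directions"),
               stringsAsFactors = FALSE),
    data.frame(name = GLRLM_NAMES, family = "textural",
               params = "distance=1;aggregation=average_over_directions",
               stringsAsFactors = FALSE))
  stopifnot(!anyDuplicated(cat$name))
  class(cat) <- c("feature_catalog", "data.frame")
  cat
}

#' @export
print.feature_catalog <- function(x, ...) {
  cat(sprintf("feature_catalog: %d features (%s)\n", nrow(x),
              paste(sprintf("%s=%d", names(table(x$family)),
                            as.integer(table(x$family))), collapse = ", ")))
  invisible(x)
}

# The 13 unique direction vectors of 26-connectivity (one per +/- pair).
DIRECTIONS_13 <- matrix(c(
  1, 0, 0,   0, 1, 0,   0, 0, 1,
  1, 1, 0,   1, -1, 0,  1, 0, 1,
  1, 0, -1,  0, 1, 1,   0, 1, -1,
  1, 1, 1,   1, 1, -1,  1, -1, 1,  1, -1, -1), ncol = 3, byrow = TRUE)
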