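# Delta features: ratios of treatment-timepoint features to simulation.

#' Delta features for one patient
#'
#' For every catalog feature `f` and post-simulation timepoint `k`,
#' `delta = f(t_k) / f(t_0)`, named `<feature>(d<k>)` where `d<k>` indexes
#' the k-th post-simulation BED level (so `morph_av_ratio(d4)` is the
#' surface-to-volume ratio change at the 54-Gy level under the default
#' timeline). Baselines with `|f(t_0)|` below `tol` give `NA` (flagged,
#' never infinite). Features whose sign can cross zero carry a
#' `ratio_unstable` attribute.
#'
#' @param fv A `feature_vectors` object from [extract_catalog()], or a
#'   timepoints x features matrix whose first row is the simulation scan.
#' @param tol Baseline magnitude below which the ratio is flagged.
#' @return Named numeric vector of length `(timepoints - 1) * catalog size`
#'   with attribute `ratio_unstable` (character vector of tagged names).
#' @export
delta_features <- function(fv, tol = 1e-8) {
  mat <- if (inherits(fv, "feature_vectors")) fv$features else fv
  if (is.null(dim(mat)) || nrow(mat) < 2)
    stop("missing simulation timepoint: need at least 2 timepoints")
  base <- mat[1, ]
  out <- numeric(0)
  for (k in 2:nrow(mat)) {
    ratio <- ifelse(abs(base) < tol, NA_real_, mat[k, ] / base)
    names(ratio) <- paste0(colnames(mat), "(d", k - 1, ")")
    out <- c(out, ratio)
  }
  unstable <- intersect(paste0(rep(RATIO_UNSTABLE, each = nrow(mat) - 1),
                               "(d", rep(seq_len(nrow(mat) - 1),
                                         length(RATIO_UNSTABLE)), ")"),
                        names(out))
  attr(out, "ratio_unstable") <- unstable
  out
}

#' Assemble the per-patient variable table
#'
#' Combines basal radiomic features, delta features and clinical
#' covariates into one modeling table (one row per patient) with an
#' outcome column `dfs2y` (1 = disease-free at 2 years, 0 = event). Each
#' column is tagged with its class (`basal`, `delta`, `clinical`) in the
#' `var_class` attribute.
#'
#' @param basal Data frame of basal features incl. `patient_id`
#'   (see [extract_cohort_features()]).
#' @param delta Data frame of delta features incl. `patient_id`.
#' @param clinical Data frame of clinical covariates incl. `patient_id`
#'   and `dfs2y`; may be `NULL` for a radiomics-only table.
#' @return Data frame of class `feature_table`.
#' @export
assemble_variable_table <- function(basal, delta, clinical = NULL) {
  ids <- basal$patient_id
  miss <- setdiff(ids, delta$patient_id)
  if (length(miss) || length(setdiff(delta$patient_id, ids)))
    stop("patients missing a feature block: ",
         paste(union(miss, setdiff(delta$patient_id, ids)), collapse = ", "))
  out <- merge(basal, delta, by = "patient_id", sort = FALSE)
  classes <- c(rep("basal", ncol(basal) - 1L), rep("delta", ncol(delta) - 1L))
  if (!is.null(clinical)) {
    if (!"dfs2y" %in% names(clinical))
      stop("clinical table must contain the outcome column 'dfs2y'")
    miss <- setdiff(ids, clinical$patient_id)
    if (length(miss))
      stop("patients missing the clinical block: ",
           paste(miss, collapse = ", "))
    out <- merge(out, clinical, by = "patient_id", sort = FALSE)
    classes <- c(classes,
                 rep("clinical", ncol(clinical) - 1L))
    classes[match("dfs2y", setdiff(names(out), "patient_id"))] <- "outcome"
  }
  names(classes) <- setdiff(names(out), "patient_id")
  attr(out, "var_class") <- classes
  class(out) <- c("feature_table", "data.frame")
  out
}

#' Variable accounting of a feature table
#'
#' @param table A `feature_table`.
#' @return Named integer vector with counts of basal, delta, clinical and
#'   total (non-outcome) variables.
#' @export
count_variables <- function(table) {
  vc <- attr(table, "var_class")
  c(basal = sum(vc == "basal"), delta = sum(vc == "delta"),
    clinical = sum(vc == "clinical"),
    total = sum(vc %in% c("basal", "delta", "clinical")))
}
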