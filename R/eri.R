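# Early regression index (ERI) from GTV volumes.

#' Early regression index
#'
#' A scalar of early fractional tumour volume regression. The default form
#' is `-log(DeltaV / V0)` with `DeltaV = V0 - Vt`: complete regression
#' (`Vt = 0`) gives 0, weaker regression gives larger values, and no
#' regression or growth (`Vt >= V0`) is flagged `NA`. Alternative published
#' forms can be registered via the `form` argument.
#'
#' @param v0 Baseline GTV volume in mm^3 (> 0).
#' @param vt GTV volume at the evaluated timepoint (>= 0).
#' @param form `"neg_log_regression"` (default) or a function `(v0, vt)`.
#' @return ERI value, or `NA` when the regression fraction is not positive.
#' @export
eri_tcp <- function(v0, vt, form = "neg_log_regression") {
  if (any(v0 <= 0)) stop("eri_tcp: v0 must be > 0")
  if (any(vt < 0)) stop("eri_tcp: vt must be >= 0")
  if (is.function(form)) return(form(v0, vt))
  stopifnot(identical(form, "neg_log_regression"))
  frac <- (v0 - vt) / v0
  ifelse(frac <= 0, NA_real_, -log(frac))
}

#' Screen ERI against outcome per BED level
#'
#' Computes per-patient ERI at every post-simulation BED level from a
#' cohort volume table and tests it against the binary 2yDFS outcome with
#' the Wilcoxon-Mann-Whitney test.
#'
#' @param volumes Data frame with columns `patient_id`, `bed_gy`,
#'   `volume_mm3` (one row per patient-timepoint; `bed_gy == 0` rows are
#'   the baselines).
#' @param outcome Named binary vector (`1` = disease-free), names are
#'   patient ids.
#' @param form Passed to [eri_tcp()].
#' @return Object of class `eri_screen`: list with `eri` (patients x
#'   levels data frame) and `pvalues` (per-level WMW p, `NA` when ERI is
#'   degenerate at that level).
#' @export
eri_screen <- function(volumes, outcome, form = "neg_log_regression") {
  stopifnot(all(c("patient_id", "bed_gy", "volume_mm3") %in% names(volumes)))
  if (length(unique(outcome)) < 2)
    stop("outcome must contain both classes")
  base <- volumes[volumes$bed_gy == 0, ]
  v0 <- stats::setNames(base$volume_mm3, base$patient_id)
  post <- volumes[volumes$bed_gy > 0, ]
  levels_gy <- sort(unique(post$bed_gy))
  eri <- data.frame(patient_id = names(v0), stringsAsFactors = FALSE)
  pvals <- stats::setNames(rep(NA_real_, length(levels_gy)),
                           paste0("bed", round(levels_gy)))
  for (k in seq_along(levels_gy)) {
    rows <- post[post$bed_gy == levels_gy[k], ]
    vt <- stats::setNames(rows$volume_mm3, rows$patient_id)[names(v0)]
    e <- eri_tcp(v0, vt, form)
    eri[[paste0("bed", round(levels_gy[k]))]] <- e
    y <- outcome[eri$patient_id]
    ok <- !is.na(e)
    if (length(unique(e[ok])) < 2 || length(unique(y[ok])) < 2) next
    pvals[k] <- wmw_test(e[ok][y[ok] == 0], e[ok][y[ok] == 1])$p.value
  }
  structure(list(eri = eri, pvalues = pvals, form = form),
            class = "eri_screen")
}
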