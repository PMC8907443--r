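#' Fractionation scheme
#'
#' Describes a uniform fractionation of the GTV prescription: dose per
#' fraction `d`, number of fractions `n`, and the alpha/beta ratio used for
#' the linear-quadratic BED conversion. For simultaneous-integrated-boost
#' plans, `dose_per_fraction` is the GTV dose per fraction, since the GTV is
#' the analyzed region.
#'
#' @param dose_per_fraction Dose per fraction in Gy (> 0).
#' @param n_fractions Total number of fractions (>= 1).
#' @param alpha_beta Alpha/beta ratio in Gy (default 10, tumour).
#' @param label Free-text label.
#' @return Object of class `fractionation_scheme`.
#' @examples
#' fpg <- fractionation_scheme(2.2, 25, label = "SIB 55/25")
#' bed_total(25, 2.2)  # 67.1 Gy
#' @export
fractionation_scheme <- function(dose_per_fraction, n_fractions,
                                 alpha_beta = 10, label = "") {
  stopifnot(dose_per_fraction > 0, n_fractions >= 1, alpha_beta > 0)
  structure(list(dose_per_fraction = dose_per_fraction,
                 n_fractions = as.integer(n_fractions),
                 alpha_beta = alpha_beta, label = label),
            class = "fractionation_scheme")
}

#' Total biologically effective dose
#'
#' `BED = n * d * (1 + d / (alpha/beta))`, linear in the number of
#' fractions for a fixed dose per fraction.
#'
#' @param n Number of fractions (>= 0).
#' @param d Dose per fraction in Gy (> 0).
#' @param alpha_beta Alpha/beta ratio in Gy (> 0).
#' @return BED in Gy.
#' @export
bed_total <- function(n, d, alpha_beta = 10) {
  if (any(n < 0) || d <= 0 || alpha_beta <= 0)
    stop("bed_total: need n >= 0, d > 0, alpha_beta > 0")
  n * d * (1 + d / alpha_beta)
}

#' Cumulative BED after each fraction of a scheme
#'
#' @param scheme A [fractionation_scheme()].
#' @return Numeric vector, entry k = BED after k fractions.
#' @export
bed_cumulative <- function(scheme) {
  stopifnot(inherits(scheme, "fractionation_scheme"))
  bed_total(seq_len(scheme$n_fractions), scheme$dose_per_fraction,
            scheme$alpha_beta)
}

#' Map a BED level to a treatment fraction
#'
#' `first_reaching` returns the first fraction whose cumulative BED reaches
#' the level (and errors if the scheme never does); `nearest` returns the
#' fraction whose cumulative BED is closest to the level (ties towards the
#' earlier fraction), which is needed for schemes whose total BED falls
#' short of the highest imaging level.
#'
#' @param scheme A [fractionation_scheme()].
#' @param level Target BED level in Gy (> 0).
#' @param rule `"nearest"` (default) or `"first_reaching"`.
#' @return Fraction index (1-based).
#' @export
fraction_for_level <- function(scheme, level,
                               rule = c("nearest", "first_reaching")) {
  rule <- match.arg(rule)
  if (level <= 0) stop("fraction_for_level: level must be > 0")
  cum <- bed_cumulative(scheme)
  if (rule == "first_reaching") {
    k <- which(cum >= level)
    if (!length(k))
      stop(sprintf("BED level %.3g Gy never reached (total %.3g Gy)",
                   level, cum[length(cum)]))
    return(k[1])
  }
  which.min(abs(cum - level))
}

#' BED timeline: imaging levels mapped onto fractions
#'
#' Builds the cumulative BED trajectory of a scheme and the mapping from
#' each target imaging level to a fraction. Defaults to the five imaging
#' levels 13, 26, 40, 54 and 67 Gy.
#'
#' @param scheme A [fractionation_scheme()].
#' @param target_levels BED levels in Gy, strictly increasing.
#' @param rule Mapping rule, see [fraction_for_level()].
#' @return Object of class `bed_timeline`: list with `cumulative`,
#'   `target_levels`, `fractions` (mapped indices) and `achieved` (the
#'   cumulative BED at the mapped fractions).
#' @export
bed_timeline <- function(scheme, target_levels = c(13, 26, 40, 54, 67),
                         rule = c("nearest", "first_reaching")) {
  rule <- match.arg(rule)
  stopifnot(length(target_levels) >= 1, all(diff(target_levels) > 0),
            all(target_levels > 0))
  cum <- bed_cumulative(scheme)
  fr <- vapply(target_levels, function(l) fraction_for_level(scheme, l, rule),
               integer(1))
  if (any(diff(fr) <= 0))
    stop("mapped fractions are not strictly increasing across levels; ",
         "target levels are too dense for this scheme")
  structure(list(scheme = scheme, cumulative = cum,
                 target_levels = target_levels, fractions = fr,
                 achieved = cum[fr], rule = rule),
            class = "bed_timeline")
}

#' @export
print.bed_timeline <- function(x, ...) {
  cat(sprintf("BED timeline (%s, %.3g Gy x %d, a/b = %.3g Gy, rule = %s)\n",
              x$scheme$label, x$scheme$dose_per_fraction,
              x$scheme$n_fractions, x$scheme$alpha_beta, x$rule))
  print(data.frame(level_gy = x$target_levels, fraction = x$fractions,
                   bed_gy = round(x$achieved, 2)), row.names = FALSE)
  invisible(x)
}
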