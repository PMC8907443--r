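# Statistical cascade: WMW screening, per-feature AUC, PCC redundancy,
# logistic models, bootstrap ROC, Youden operating point.

#' Wilcoxon-Mann-Whitney rank-sum test (two-sided)
#'
#' `auto` uses exact enumeration (via the exact null U distribution) when
#' the pooled sample size is at most 12 and there are no ties, otherwise a
#' tie-corrected normal approximation with continuity correction. Two
#' identical samples give p = 1.
#'
#' @param x,y Numeric vectors, both nonempty (x = one outcome group,
#'   y = the other).
#' @param mode `"auto"`, `"exact"` or `"normal_approx_tie_corrected"`.
#' @return List with `statistic` (U of `x`), `p.value`, `method`.
#' @export
wmw_test <- function(x, y, mode = c("auto", "exact",
                                    "normal_approx_tie_corrected")) {
  mode <- match.arg(mode)
  n1 <- length(x); n2 <- length(y)
  if (!n1 || !n2) stop("both groups must be nonempty")
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- table(c(x, y))
  has_ties <- any(ties > 1)
  if (length(ties) == 1) # all values identical across both groups
    return(list(statistic = U, p.value = 1, method = "degenerate"))
  if (mode == "exact" && has_ties)
    stop("exact mode requires untied data")
  use_exact <- mode == "exact" ||
    (mode == "auto" && !has_ties && n1 + n2 <= 12)
  if (use_exact) {
    p <- 2 * min(pwilcox(U, n1, n2),
                 1 - pwilcox(U - 1, n1, n2))
    return(list(statistic = U, p.value = min(1, p), method = "exact"))
  }
  n <- n1 + n2
  tiecor <- sum(ties^3 - ties) / (n * (n - 1))
  sigma2 <- n1 * n2 / 12 * ((n + 1) - tiecor)
  if (sigma2 <= 0)
    return(list(statistic = U, p.value = 1, method = "degenerate"))
  z <- (U - n1 * n2 / 2)
  z <- sign(z) * max(0, abs(z) - 0.5) / sqrt(sigma2)
  list(statistic = U, p.value = min(1, 2 * pnorm(-abs(z))),
       method = "normal_approx_tie_corrected")
}

#' Per-feature AUC (pair-counting)
#'
#' Probability that a random event-class value exceeds a random
#' non-event-class value, ties counted 1/2 (equals `U / (n1 * n0)`).
#' Because a delta feature may predict in either direction, the oriented
#' AUC `max(a, 1 - a)` is reported with the direction retained.
#'
#' @param values Numeric vector.
#' @param labels Binary vector, 1 = event class.
#' @return List with `auc` (oriented), `auc_raw`, `direction` (+1 if
#'   events have larger values) and `U`.
#' @export
feature_auc <- function(values, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (!n1 || !n0) stop("both classes must be present")
  r <- rank(values)
  U <- sum(r[labels == 1]) - n1 * (n1 + 1) / 2
  a <- U / (n1 * n0)
  list(auc = max(a, 1 - a), auc_raw = a,
       direction = if (a >= 0.5) 1L else -1L, U = U)
}

#' Pearson correlation coefficient
#'
#' @param x,y Numeric vectors of equal length >= 3 with nonzero variance.
#' @return Correlation in `[-1, 1]`.
#' @export
pcc <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3)
    stop("pcc needs >= 3 paired points")
  if (var(x) == 0 || var(y) == 0)
    stop("pcc undefined for zero-variance input")
  cor(x, y)
}

#' Univariate screening of a feature table
#'
#' For every non-outcome variable: WMW p-value of event vs non-event
#' groups and oriented AUC; variables are ranked by p ascending with ties
#' broken by AUC descending. Constant columns and columns missing in more
#' than `max_missing` of patients are flagged and excluded from ranking.
#' A PCC matrix is computed over the significant (p < alpha) variables.
#' No multiplicity correction is applied (mirroring raw univariate
#' reporting); the expected false-positive count `alpha * n_tested` is
#' returned for transparency.
#'
#' @param table A `feature_table` from [assemble_variable_table()], or any
#'   data frame with a `dfs2y` column (1 = disease-free, 0 = event).
#' @param alpha Significance level (default 0.05).
#' @param max_missing Maximum tolerated missing fraction per variable
#'   (default 0.2); beyond it the variable is dropped.
#' @return Object of class `screening_result`.
#' @export
screen_features <- function(table, alpha = 0.05, max_missing = 0.2) {
  if (!"dfs2y" %in% names(table)) stop("table must contain 'dfs2y'")
  y_event <- 1L - as.integer(table$dfs2y)
  if (length(unique(y_event)) < 2) stop("outcome must have both classes")
  vc <- attr(table, "var_class")
  vars <- setdiff(names(table), c("patient_id", "dfs2y"))
  n <- nrow(table)
  res <- data.frame(variable = vars,
                    class = if (!is.null(vc)) unname(vc[vars]) else NA,
                    p = NA_real_, auc = NA_real_, direction = NA_integer_,
                    status = "ok", stringsAsFactors = FALSE)
  for (i in seq_along(vars)) {
    v <- table[[vars[i]]]
    if (!is.numeric(v)) v <- as.numeric(as.factor(v))
    ok <- !is.na(v)
    if (mean(!ok) > max_missing) { res$status[i] <- "missing"; next }
    if (length(unique(v[ok])) < 2) { res$status[i] <- "constant"; next }
    ye <- y_event[ok]
    if (length(unique(ye)) < 2) { res$status[i] <- "degenerate"; next }
    res$p[i] <- wmw_test(v[ok][ye == 1], v[ok][ye == 0])$p.value
    fa <- feature_auc(v[ok], ye)
    res$auc[i] <- fa$auc
    res$direction[i] <- fa$direction
  }
  usable <- res$status == "ok"
  res$significant <- usable & !is.na(res$p) & res$p < alpha
  res$rank <- NA_integer_
  ord <- order(res$p, -res$auc, na.last = TRUE)
  ord <- ord[usable[ord]]
  res$rank[ord] <- seq_along(ord)
  sig_vars <- res$variable[res$significant]
  pcc_mat <- NULL
  if (length(sig_vars) >= 2) {
    m <- sapply(table[sig_vars], function(v)
      if (is.numeric(v)) v else as.numeric(as.factor(v)))
    pcc_mat <- suppressWarnings(cor(m, use = "pairwise.complete.obs"))
  }
  structure(list(table = res[order(res$rank, na.last = TRUE), ],
                 pcc = pcc_mat, alpha = alpha,
                 n_tested = sum(usable),
                 expected_false_positives = alpha * sum(usable)),
            class = "screening_result")
}

#' @export
print.screening_result <- function(x, ...) {
  cat(sprintf("screening: %d variables tested, %d significant at p < %g\n",
              x$n_tested, sum(x$table$significant, na.rm = TRUE), x$alpha))
  cat(sprintf("expected false positives under the global null: %.1f\n",
              x$expected_false_positives))
  print(utils::head(x$table[, c("variable", "class", "p", "auc", "rank")],
                    10), row.names = FALSE)
  invisible(x)
}

#' Select the lowest-PCC pair anchored at the top feature
#'
#' Among the significant delta features, the single most significant one
#' is fixed and the partner minimizing the absolute mutual Pearson
#' correlation is chosen from the `top_k` next-ranked significant delta
#' features (ties broken by rank). With fewer than two significant
#' features the top feature alone is returned with a warning.
#'
#' @param sr A `screening_result`.
#' @param top_k Size of the candidate partner pool (default all).
#' @param class_filter Variable class to search within (default
#'   `"delta"`; `NULL` for all classes).
#' @return Character vector of one or two variable names.
#' @export
select_pair <- function(sr, top_k = Inf, class_filter = "delta") {
  stopifnot(inherits(sr, "screening_result"))
  tab <- sr$table
  sig <- tab[tab$significant %in% TRUE, ]
  if (!is.null(class_filter) && "class" %in% names(sig) &&
      !all(is.na(sig$class)))
    sig <- sig[sig$class %in% class_filter, ]
  sig <- sig[order(sig$rank), ]
  if (nrow(sig) < 1) stop("no significant feature to anchor the pair")
  if (nrow(sig) < 2) {
    warning("fewer than 2 significant features; falling back to single")
    return(sig$variable[1])
  }
  anchor <- sig$variable[1]
  partners <- utils::head(sig$variable[-1], top_k)
  rho <- abs(sr$pcc[anchor, partners])
  best <- partners[order(rho, match(partners, sig$variable))][1]
  c(anchor, best)
}

#' Logistic regression by IRLS with a separation-safe ridge fallback
#'
#' Predictors are standardized internally; coefficients are reported on
#' both the standardized and the original scale. When (quasi-)complete
#' separation is detected (diverging standardized coefficients or fitted
#' probabilities collapsing to 0/1), the model is refit with a small ridge
#' penalty on the standardized slopes and flagged.
#'
#' @param X Numeric matrix or data frame of predictors (no constant
#'   columns).
#' @param y Binary response vector (1 = event).
#' @param ridge Ridge penalty used by the fallback (default 0.1).
#' @param max_iter IRLS iteration cap.
#' @return Object of class `logistic_fit` with elements `coefficients`
#'   (original scale), `coefficients_std`, `fitted`, `separation`,
#'   `penalized`, `converged`.
#' @export
fit_logistic <- function(X, y, ridge = 0.1, max_iter = 100L) {
  y <- as.numeric(y)
  if (is.null(X) || (is.data.frame(X) && ncol(X) == 0)) {
    X <- matrix(numeric(0), length(y), 0)
  }
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  n <- length(y)
  if (nrow(X) != n) stop("X and y dimensions disagree")
  if (ncol(X) > 0 && any(apply(X, 2, sd) == 0))
    stop("constant predictor column")
  if (n <= ncol(X) + 1) stop("need n > #predictors + 1")
  mu_x <- if (ncol(X)) colMeans(X) else numeric(0)
  sd_x <- if (ncol(X)) apply(X, 2, sd) else numeric(0)
  Z <- cbind(`(Intercept)` = rep(1, n),
             if (ncol(X)) sweep(sweep(X, 2, mu_x), 2, sd_x, `/`))
  irls <- function(lambda) {
    beta <- rep(0, ncol(Z))
    pen <- c(0, rep(lambda, ncol(Z) - 1))
    for (it in seq_len(max_iter)) {
      eta <- drop(Z %*% beta)
      p <- plogis(eta)
      w <- pmax(p * (1 - p), 1e-10)
      zresp <- eta + (y - p) / w
      H <- crossprod(Z, Z * w) + diag(pen, ncol(Z))
      beta_new <- tryCatch(solve(H, crossprod(Z, w * zresp)),
                           error = function(e) NULL)
      if (is.null(beta_new)) return(list(beta = beta, converged = FALSE))
      delta <- max(abs(beta_new - beta))
      beta <- drop(beta_new)
      if (delta < 1e-9) return(list(beta = beta, converged = TRUE))
    }
    list(beta = beta, converged = FALSE)
  }
  fit <- irls(0)
  p_hat <- plogis(drop(Z %*% fit$beta))
  separated <- !fit$converged ||
    max(abs(fit$beta[-1]), 0) > 15 ||
    (ncol(Z) > 1 && all(abs(y - p_hat) < 1e-6))
  penalized <- FALSE
  if (separated) {
    fit <- irls(ridge)
    penalized <- TRUE
    if (!fit$converged)
      stop("logistic fit did not converge even with ridge penalty ", ridge)
    p_hat <- plogis(drop(Z %*% fit$beta))
  }
  beta_std <- fit$beta
  beta_orig <- beta_std
  if (ncol(X)) {
    beta_orig[-1] <- beta_std[-1] / sd_x
    beta_orig[1] <- beta_std[1] - sum(beta_std[-1] * mu_x / sd_x)
    names(beta_orig) <- c("(Intercept)", colnames(X))
    names(beta_std) <- c("(Intercept)", colnames(X))
  }
  structure(list(coefficients = beta_orig, coefficients_std = beta_std,
                 fitted = p_hat, separation = separated,
                 penalized = penalized, converged = fit$converged),
            class = "logistic_fit")
}

#' ROC analysis with bootstrap CI and Youden operating point
#'
#' Empirical ROC over all score thresholds (positive when score >=
#' threshold); trapezoid AUC (equal to pair counting); 95 percent
#' percentile bootstrap CI over class-stratified patient resamples; the
#' operating threshold maximizes the Youden index `J = sens + spec - 1`,
#' ties broken towards higher specificity. Scores predicting in the
#' anti-direction (raw AUC < 0.5) are flipped first and flagged.
#'
#' @param score Numeric per-patient score.
#' @param y Binary outcome, 1 = event (positive class).
#' @param n_boot Bootstrap iterations (default 2000).
#' @param conf Confidence level (default 0.95).
#' @param orient Flip anti-predictive scores (default TRUE).
#' @return Object of class `model_report`.
#' @export
roc_analysis <- function(score, y, n_boot = 2000L, conf = 0.95,
                         orient = TRUE) {
  y <- as.integer(y)
  stopifnot(length(score) == length(y), n_boot >= 1)
  if (length(unique(y)) < 2) stop("both classes must be present")
  raw <- feature_auc(score, y)
  flipped <- FALSE
  if (orient && raw$auc_raw < 0.5) {
    score <- -score
    flipped <- TRUE
  }
  thr <- sort(unique(score))
  thr <- c(thr, Inf)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  sens <- vapply(thr, function(t) sum(score >= t & y == 1) / n1, numeric(1))
  spec <- vapply(thr, function(t) sum(score < t & y == 0) / n0, numeric(1))
  roc <- data.frame(threshold = thr, sensitivity = sens, specificity = spec)
  # trapezoid over the (FPR, TPR) polyline, anchored at (0,0) and (1,1)
  fpr <- c(1, 1 - spec)
  tpr <- c(1, sens)
  ord <- order(fpr, tpr)
  auc_trap <- sum(diff(fpr[ord]) * (utils::head(tpr[ord], -1) +
                                    utils::tail(tpr[ord], -1)) / 2)
  draws <- cpp_boot_auc(score[y == 1], score[y == 0], as.integer(n_boot))
  # BCa interval: the plain percentile interval undercovers for the AUC
  # at small event counts; bias correction + jackknife acceleration
  # restores nominal-range coverage
  z0 <- qnorm(clamp(mean(draws < auc_trap) + 0.5 * mean(draws == auc_trap),
                    1e-4, 1 - 1e-4))
  jk <- vapply(seq_along(y), function(i) {
    yy <- y[-i]
    if (length(unique(yy)) < 2) return(NA_real_)
    feature_auc(score[-i], yy)$auc_raw
  }, numeric(1))
  jk <- jk[!is.na(jk)]
  dj <- mean(jk) - jk
  accel <- sum(dj^3) / (6 * sum(dj^2)^1.5 + 1e-12)
  za <- qnorm(c((1 - conf) / 2, 1 - (1 - conf) / 2))
  probs <- pnorm(z0 + (z0 + za) / (1 - accel * (z0 + za)))
  qs <- quantile(draws, probs, names = FALSE)
  ci <- c(min(qs[1], auc_trap), max(qs[2], auc_trap))
  J <- sens + spec - 1
  best <- which(J == max(J))
  best <- best[order(-spec[best])][1]
  structure(list(roc = roc, auc = auc_trap, auc_ci = ci,
                 threshold = thr[best], sensitivity = sens[best],
                 specificity = spec[best], j_index = J[best],
                 n_boot = n_boot, conf = conf, flipped = flipped,
                 boot_draws_summary = summary(draws)),
            class = "model_report")
}

#' @export
print.model_report <- function(x, ...) {
  cat(sprintf(paste0("AUC %.3f (%.0f%% CI %.3f-%.3f), threshold %.3f, ",
                     "sens %.3f, spec %.3f, J %.3f%s\n"),
              x$auc, 100 * x$conf, x$auc_ci[1], x$auc_ci[2], x$threshold,
              x$sensitivity, x$specificity, x$j_index,
              if (isTRUE(x$flipped)) " (orientation flipped)" else ""))
  invisible(x)
}

#' Build the three predictive model reports
#'
#' Produces the standard report layout: a clinical-only model on the
#' chemotherapy covariate, a single-feature model on the most significant
#' delta radiomic feature, and the combined chemotherapy + delta-feature
#' model. Scores are fitted logistic probabilities; each score goes
#' through [roc_analysis()]. A constant chemotherapy column skips the
#' clinical-only and combined rows with a warning.
#'
#' @param table A `feature_table` with outcome `dfs2y` and a chemotherapy
#'   covariate column.
#' @param chemo_var Name of the chemotherapy column (default
#'   `"chemo_with_oxa"`).
#' @param alpha Screening significance level.
#' @param n_boot Bootstrap iterations per model.
#' @param screening Optional precomputed `screening_result`.
#' @return Object of class `model_set`: list with `screening`, `models`
#'   (named list of `model_report`), `best_feature`, `table2`
#'   (report-style data frame).
#' @export
build_models <- function(table, chemo_var = "chemo_with_oxa", alpha = 0.05,
                         n_boot = 2000L, screening = NULL) {
  if (is.null(screening)) screening <- screen_features(table, alpha)
  y_event <- 1L - as.integer(table$dfs2y)
  tab <- screening$table
  delta_sig <- tab[tab$significant %in% TRUE & tab$class %in% "delta", ]
  if (!nrow(delta_sig)) {
    # tiny cohorts can leave nothing below alpha; fall back to the
    # best-ranked delta feature so the report still has its three rows
    warning("no delta feature significant at alpha = ", alpha,
            "; using the top-ranked delta feature")
    delta_sig <- tab[tab$class %in% "delta" & !is.na(tab$rank), ]
    if (!nrow(delta_sig)) stop("no usable delta feature")
  }
  best <- delta_sig$variable[which.min(delta_sig$rank)]
  models <- list()

  fit_and_roc <- function(X) {
    X <- as.matrix(X)
    keep <- stats::complete.cases(X)
    fit <- fit_logistic(X[keep, , drop = FALSE], y_event[keep])
    rep <- roc_analysis(fit$fitted, y_event[keep], n_boot = n_boot)
    rep$fit <- fit
    rep
  }

  chemo_ok <- chemo_var %in% names(table) &&
    length(unique(table[[chemo_var]])) > 1
  if (chemo_ok) {
    models$clinical_only <-
      fit_and_roc(stats::setNames(table[chemo_var], chemo_var))
  } else {
    warning("chemotherapy column missing or constant; ",
            "clinical-only and combined models skipped")
  }
  models$single_best <- fit_and_roc(stats::setNames(table[best], best))
  if (chemo_ok) {
    models$combined <- fit_and_roc(table[c(chemo_var, best)])
  }

  t2 <- do.call(rbind, lapply(names(models), function(nm) {
    m <- models[[nm]]
    data.frame(Model = switch(nm, clinical_only = "Chemo",
                              single_best = best,
                              combined = paste0("Chemo+", best)),
               Sensitivity = m$sensitivity, Specificity = m$specificity,
               Threshold = m$threshold, J_index = m$j_index, AUC = m$auc,
               AUC_Low = m$auc_ci[1], AUC_High = m$auc_ci[2],
               stringsAsFactors = FALSE)
  }))
  structure(list(screening = screening, models = models,
                 best_feature = best, table2 = t2),
            class = "model_set")
}

#' @export
print.model_set <- function(x, ...) {
  cat("best delta feature:", x$best_feature, "\n")
  print(x$table2, row.names = FALSE, digits = 3)
  invisible(x)
}
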