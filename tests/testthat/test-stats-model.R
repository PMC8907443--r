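test_that("WMW exact mode matches full enumeration on toys", {
  r <- wmw_test(c(1, 2), c(3, 4), mode = "exact")
  expect_equal(r$p.value, 1 / 3)                 # 2 of 6 rank splits
  expect_equal(r$p.value, wmw_enumerate(c(1, 2), c(3, 4)))
  set.seed(14)
  for (i in 1:10) {
    x <- rnorm(sample(2:5, 1))
    y <- rnorm(sample(2:5, 1))
    expect_equal(wmw_test(x, y, mode = "exact")$p.value,
                 wmw_enumerate(x, y), tolerance = 1e-12)
  }
})

test_that("WMW matches wilcox.test as an independent oracle", {
  set.seed(15)
  for (i in 1:20) {
    x <- rnorm(sample(8:30, 1))
    y <- rnorm(sample(8:30, 1), mean = runif(1, -1, 1))
    if (i %% 2 == 0) { # induce ties
      x <- round(x); y <- round(y)
    }
    ours <- wmw_test(x, y)
    ref <- suppressWarnings(wilcox.test(x, y, exact = FALSE,
                                        correct = TRUE))
    expect_equal(ours$statistic, unname(ref$statistic))
    if (ours$method == "normal_approx_tie_corrected")
      expect_equal(ours$p.value, ref$p.value, tolerance = 1e-9)
  }
  expect_equal(wmw_test(c(1, 2, 3), c(1, 2, 3))$p.value, 1)
  expect_equal(wmw_test(rep(4, 5), rep(4, 7))$p.value, 1)
})

test_that("WMW type-I error is calibrated at large samples", {
  set.seed(16)
  rej <- mean(replicate(2000, {
    wmw_test(rnorm(50), rnorm(50))$p.value < 0.05
  }))
  expect_gt(rej, 0.03)
  expect_lt(rej, 0.07)
})

test_that("AUC equals brute-force pair counting and U-duality holds", {
  expect_equal(feature_auc(c(1, 2, 3), c(0, 0, 1))$auc, 1)
  expect_equal(feature_auc(rep(2, 6), c(0, 1, 0, 1, 0, 1))$auc_raw, 0.5)
  set.seed(17)
  for (i in 1:50) {
    n <- 20
    v <- sample(1:8, n, replace = TRUE)   # heavy ties
    y <- rbinom(n, 1, 0.4)
    if (length(unique(y)) < 2) next
    fa <- feature_auc(v, y)
    expect_equal(fa$auc_raw, auc_bruteforce(v, y), tolerance = 1e-12)
    n1 <- sum(y == 1); n0 <- sum(y == 0)
    expect_equal(fa$U, wmw_test(v[y == 1], v[y == 0])$statistic)
    expect_equal(fa$auc_raw * n1 * n0, fa$U, tolerance = 1e-9)
    expect_gte(fa$auc, 0.5)
  }
})

test_that("pcc equals the covariance formula and validates input", {
  x <- c(1, 3, 4, 7, 9)
  y <- c(2, 1, 5, 8, 8)
  byhand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(pcc(x, y), byhand, tolerance = 1e-12)
  expect_equal(pcc(x, 2 * x + 1), 1)
  expect_equal(pcc(x, -x), -1)
  expect_error(pcc(x, rep(1, 5)), "zero-variance")
  expect_error(pcc(1:2, 1:2), "3 paired")
})

test_that("screening ranks a separating feature first and flags junk", {
  set.seed(18)
  n <- 30
  y <- rep(c(1, 0), c(22, 8))
  tab <- data.frame(patient_id = sprintf("p%02d", 1:n),
                    perfect = y * 10 + seq_len(n) / 100,
                    noise1 = rnorm(n), noise2 = rnorm(n),
                    constant = 1,
                    mostly_missing = c(rnorm(5), rep(NA, n - 5)),
                    dfs2y = y)
  sr <- screen_features(tab)
  expect_identical(sr$table$variable[1], "perfect")
  expect_equal(sr$table$auc[1], 1)
  stat <- sr$table$status[match(c("constant", "mostly_missing"),
                                sr$table$variable)]
  expect_identical(stat, c("constant", "missing"))
  expect_true(all(is.na(sr$table$rank[sr$table$status != "ok"])))
  expect_equal(sr$expected_false_positives, 0.05 * sr$n_tested)
})

test_that("screening false-positive rate tracks alpha under the null", {
  set.seed(19)
  rates <- replicate(20, {
    n <- 48
    y <- rbinom(n, 1, 5 / 6)
    while (length(unique(y)) < 2) y <- rbinom(n, 1, 5 / 6)
    tab <- as.data.frame(matrix(rnorm(n * 500), n))
    tab$dfs2y <- y
    sr <- screen_features(tab)
    mean(sr$table$significant)
  })
  expect_lt(abs(mean(rates) - 0.05), 0.02)
})

test_that("select_pair agrees with exhaustive search over the pool", {
  set.seed(20)
  n <- 40
  y <- rbinom(n, 1, 0.5)
  base <- y + rnorm(n, sd = 0.4)
  # f1 strongest; f2 a near-copy of f1; f3 informative but decorrelated
  tab <- data.frame(patient_id = seq_len(n),
                    f1 = base,
                    f2 = base + rnorm(n, sd = 0.05),
                    f3 = y + rnorm(n, sd = 0.6) + 0.8 * rnorm(n),
                    dfs2y = y)
  attr(tab, "var_class") <- c(f1 = "delta", f2 = "delta", f3 = "delta",
                              dfs2y = "outcome")
  sr <- screen_features(tab)
  if (sum(sr$table$significant) >= 2) {
    pair <- select_pair(sr)
    anchor <- sr$table$variable[1]
    sig <- sr$table$variable[sr$table$significant]
    partners <- setdiff(sig, anchor)
    best <- partners[which.min(abs(sr$pcc[anchor, partners]))]
    expect_identical(pair, c(anchor, best))
  }
  # two significant features -> that pair
  tab2 <- tab[, c("patient_id", "f1", "f3", "dfs2y")]
  attr(tab2, "var_class") <- c(f1 = "delta", f3 = "delta",
                               dfs2y = "outcome")
  sr2 <- screen_features(tab2)
  if (sum(sr2$table$significant) == 2)
    expect_setequal(select_pair(sr2), c("f1", "f3"))
})

test_that("logistic fit recovers known coefficients and handles edges", {
  set.seed(22)
  n <- 5000
  x <- rnorm(n)
  beta <- c(-1, 0.8)
  y <- rbinom(n, 1, plogis(beta[1] + beta[2] * x))
  fit <- fit_logistic(matrix(x, ncol = 1, dimnames = list(NULL, "x")), y)
  expect_false(fit$penalized)
  expect_lt(abs(fit$coefficients["x"] - beta[2]) / beta[2], 0.05)
  expect_lt(abs(fit$coefficients[1] - beta[1]) / abs(beta[1]), 0.05)
  # agreement with glm on the same data
  ref <- glm(y ~ x, family = binomial())
  expect_equal(unname(fit$coefficients), unname(coef(ref)),
               tolerance = 1e-6)

  # intercept-only: fitted probability equals prevalence
  f0 <- fit_logistic(NULL, y)
  expect_equal(unique(round(f0$fitted, 10)), round(mean(y), 10))

  # perfect separation: flagged, penalized, finite
  ys <- rep(0:1, each = 10)
  xs <- matrix(c(1:10, 21:30), ncol = 1, dimnames = list(NULL, "x"))
  fs <- fit_logistic(xs, ys)
  expect_true(fs$separation)
  expect_true(fs$penalized)
  expect_true(all(is.finite(fs$coefficients)))
  expect_error(fit_logistic(matrix(1, 10, 1), rbinom(10, 1, 0.5)),
               "constant")
})

test_that("ROC analysis matches exhaustive threshold enumeration", {
  score <- c(0.1, 0.4, 0.35, 0.8, 0.7, 0.2)
  y <- c(0, 0, 1, 1, 1, 0)
  set.seed(23)
  rep <- roc_analysis(score, y, n_boot = 200)
  # brute force over all thresholds
  thr <- sort(unique(score))
  sens <- vapply(thr, function(t) mean(score[y == 1] >= t), numeric(1))
  spec <- vapply(thr, function(t) mean(score[y == 0] < t), numeric(1))
  J <- sens + spec - 1
  expect_equal(rep$j_index, max(J))
  best <- which(J == max(J))
  expect_equal(rep$sensitivity, sens[best[order(-spec[best])][1]])
  expect_equal(rep$auc, auc_bruteforce(score, y), tolerance = 1e-12)
  expect_true(rep$auc_ci[1] <= rep$auc && rep$auc <= rep$auc_ci[2])

  # perfect and anti-predictive scores
  set.seed(24)
  yp <- c(0, 0, 0, 1, 1)
  perf <- roc_analysis(c(1, 2, 3, 9, 10), yp, n_boot = 50)
  expect_equal(perf$auc, 1)
  expect_equal(perf$auc_ci, c(1, 1))
  expect_equal(perf$sensitivity, 1)
  expect_equal(perf$specificity, 1)
  expect_equal(perf$j_index, 1)
  anti <- roc_analysis(-c(1, 2, 3, 9, 10), yp, n_boot = 50)
  expect_true(anti$flipped)
  expect_equal(anti$auc, 1)
})

test_that("trapezoid AUC equals pair counting on random tied instances", {
  set.seed(25)
  for (i in 1:30) {
    n <- sample(8:40, 1)
    score <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)
    y <- rbinom(n, 1, 0.4)
    if (length(unique(y)) < 2) next
    rep <- roc_analysis(score, y, n_boot = 1, orient = FALSE)
    expect_equal(rep$auc, auc_bruteforce(score, y), tolerance = 1e-12)
  }
})

test_that("bootstrap AUC CI coverage is calibrated at n = 48", {
  # binormal scores tuned to a true AUC of 0.8: mu = sqrt(2)*qnorm(0.8)
  mu <- sqrt(2) * qnorm(0.8)
  set.seed(26)
  cover <- replicate(500, {
    y <- rep(c(1, 0), c(8, 40))
    s <- rnorm(48, mean = mu * y)
    rep <- roc_analysis(s, y, n_boot = 2000, orient = FALSE)
    rep$auc_ci[1] <= 0.8 && 0.8 <= rep$auc_ci[2]
  })
  expect_gte(mean(cover), 0.90)
  expect_lte(mean(cover), 0.98)
})

test_that("build_models produces the three report rows on a synthetic table", {
  co <- simulate_cohort(tiny_config(n = 16, seed = 5), images = FALSE)
  basal <- extract_cohort_features(co)
  delta <- deltarad:::delta_from_basal(basal)
  tab <- assemble_variable_table(basal, delta,
                                 deltarad:::clinical_design(co$clinical))
  set.seed(2)
  ms <- build_models(tab, n_boot = 200)
  expect_setequal(names(ms$models),
                  c("clinical_only", "single_best", "combined"))
  expect_identical(nrow(ms$table2), 3L)
  expect_identical(names(ms$table2),
                   c("Model", "Sensitivity", "Specificity", "Threshold",
                     "J_index", "AUC", "AUC_Low", "AUC_High"))
  for (m in ms$models) {
    expect_true(m$auc_ci[1] <= m$auc && m$auc <= m$auc_ci[2])
    expect_equal(m$j_index, m$sensitivity + m$specificity - 1)
  }
  # constant chemo column -> clinical rows skipped with a warning
  tab$chemo_with_oxa <- 0
  set.seed(2)
  expect_warning(ms2 <- build_models(tab, n_boot = 50), "constant")
  expect_identical(names(ms2$models), "single_best")
})
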