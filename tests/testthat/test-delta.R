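test_that("delta of an unchanged series is 1 everywhere finite", {
  tv <- toy_volume_mask(seed = 8)
  s <- patient_series("T", list(tv$volume, tv$volume, tv$volume),
                      list(tv$mask, tv$mask, tv$mask),
                      c(0, 13.4, 26.8), tv$spacing)
  fv <- extract_catalog(s)
  d <- delta_features(fv)
  expect_identical(length(d), 2L * 97L)
  finite <- !is.na(d)
  expect_true(all(abs(d[finite] - 1) < 1e-12))
  expect_true(all(grepl("\\(d[12]\\)$", names(d))))
})

test_that("volume halving and shrinking spheres give the analytic deltas", {
  b10 <- digitize_ball(10, 1, pad = 3)
  half <- b10
  half[1:ceiling(dim(b10)[1] / 2 - 0.5), , ] <- FALSE
  m10 <- morphology_features(b10, c(1, 1, 1))

  # exact ratio definition on a hand-built matrix
  mat <- rbind(c(1000, 10), c(500, 12))
  colnames(mat) <- c("morph_volume", "x")
  d <- delta_features(mat)
  expect_equal(unname(d["morph_volume(d1)"]), 0.5)
  expect_equal(unname(d["x(d1)"]), 1.2)

  # sphere r=10 at simulation, r=5 at the 4th level: AV doubles
  b5 <- digitize_ball(5, 1, pad = 8)
  m5 <- morphology_features(b5, c(1, 1, 1))
  av_ratio <- unname(m5["morph_av_ratio"] / m10["morph_av_ratio"])
  expect_equal(av_ratio, 2, tolerance = 0.08)
})

test_that("near-zero baselines are flagged, never infinite", {
  mat <- rbind(c(0, 1e-12, 2), c(1, 1, 4))
  colnames(mat) <- c("a", "b", "c")
  d <- delta_features(mat)
  expect_true(is.na(d["a(d1)"]))
  expect_true(is.na(d["b(d1)"]))
  expect_equal(unname(d["c(d1)"]), 2)
  expect_error(delta_features(mat[1, , drop = FALSE]), "simulation")
})

test_that("ratio-unstable features are tagged", {
  co <- simulate_cohort(tiny_config(n = 2))
  d <- delta_features(extract_catalog(co$series[[1]]))
  tags <- attr(d, "ratio_unstable")
  expect_true("fo_skewness(d1)" %in% tags)
  expect_true(any(grepl("cluster_shade", tags)))
  expect_false(any(grepl("morph_volume", tags)))
})

test_that("variable table accounting matches the catalog arithmetic", {
  co <- simulate_cohort(tiny_config(n = 3))
  basal <- extract_cohort_features(co)
  delta <- deltarad:::delta_from_basal(basal)
  expect_identical(ncol(basal) - 1L, 582L)
  expect_identical(ncol(delta) - 1L, 485L)

  clin32 <- data.frame(patient_id = basal$patient_id,
                       matrix(rnorm(nrow(basal) * 32), nrow(basal), 32),
                       dfs2y = c(1, 1, 0))
  tab <- assemble_variable_table(basal, delta, clin32)
  expect_identical(unname(count_variables(tab)),
                   c(582L, 485L, 32L, 1099L))
  tab0 <- assemble_variable_table(basal, delta, NULL)
  expect_identical(unname(count_variables(tab0)["total"]), 1067L)
  expect_identical(nrow(tab), 3L)

  expect_error(assemble_variable_table(basal[-1, ], delta, clin32),
               "missing")
})

test_that("delta of intensity-scale-invariant features survives rescaling", {
  co <- simulate_cohort(tiny_config(n = 2))
  s <- co$series[[1]]
  s2 <- s
  s2$volumes <- lapply(s$volumes, function(v) 2.5 * v + 10)
  d1 <- delta_features(extract_catalog(s))
  d2 <- delta_features(extract_catalog(s2))
  # z-score normalization + fixed bin count make every finite delta match
  ok <- !is.na(d1) & !is.na(d2)
  expect_gt(mean(ok), 0.9)
  expect_equal(d1[ok], d2[ok], tolerance = 1e-8)
})
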