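test_that("GLCM of a 1D alternating strip matches the hand-built matrix", {
  vol <- array(c(1, 2, 1, 2), c(4, 1, 1))
  mask <- array(TRUE, c(4, 1, 1))
  la <- deltarad:::levels_array(vol, mask, discretization_params(n_bins = 2))
  m <- deltarad:::glcm_matrix(la$levels, c(1, 0, 0), la$n_levels)
  expect_equal(m, matrix(c(0, 0.5, 0.5, 0), 2, 2))
  s <- deltarad:::glcm_stats(m)
  expect_equal(unname(s["contrast"]), 1)
  expect_equal(unname(s["max_probability"]), 0.5)
  expect_equal(unname(s["joint_entropy"]), 1)     # two cells at 1/2
  expect_equal(unname(s["dissimilarity"]), 1)
  expect_equal(unname(s["correlation"]), -1)      # perfect alternation
})

test_that("constant ROI gives the degenerate GLCM conventions", {
  vol <- array(4, c(4, 4, 4))
  mask <- array(TRUE, c(4, 4, 4))
  g <- glcm_features(vol, mask, distances = 1L)
  expect_equal(unname(g["glcm_joint_energy_d1"]), 1)
  expect_equal(unname(g["glcm_contrast_d1"]), 0)
  expect_equal(unname(g["glcm_joint_entropy_d1"]), 0)
  expect_true(is.na(g["glcm_correlation_d1"]))
})

test_that("co-occurrence matrices are symmetric for every direction", {
  tv <- toy_volume_mask(seed = 7)
  la <- deltarad:::levels_array(tv$volume, tv$mask, discretization_params())
  counts <- deltarad:::cpp_glcm_counts(la$levels, dim(la$levels),
                                       deltarad:::DIRECTIONS_13,
                                       la$n_levels)
  for (d in seq_len(dim(counts)[3]))
    expect_identical(counts[, , d], t(counts[, , d]))
})

test_that("GLCM features agree with skimage graycomatrix on a 2D texture", {
  set.seed(21)
  img <- matrix(sample(0:7, 12 * 12, replace = TRUE), 12, 12)
  vol <- array(img, c(12, 12, 1))
  mask <- array(TRUE, c(12, 12, 1))
  la <- deltarad:::levels_array(vol, mask, discretization_params(n_bins = 8))
  # offset (1,0,0) walks the first array axis == numpy axis 0 == skimage
  # angle pi/2 (with symmetric=TRUE the sign is immaterial)
  P <- deltarad:::glcm_matrix(la$levels, c(1, 0, 0), 8)
  f <- tempfile(fileext = ".txt")
  write(t(img), f, ncolumns = 12)
  py <- sprintf("
import numpy as np
from skimage.feature import graycomatrix, graycoprops
img = np.loadtxt('%s').astype(int)
g = graycomatrix(img, [1], [np.pi/2], levels=8, symmetric=True, normed=True)
P = g[:, :, 0, 0]
for v in P.ravel():
    print('%%.12f' %% v)
for p in ['contrast', 'dissimilarity', 'energy', 'correlation']:
    print('%%.12f' %% float(graycoprops(g, p)[0, 0]))
", f)
  out <- as.numeric(system2("python", c("-c", shQuote(py)), stdout = TRUE))
  ref <- matrix(out[1:64], 8, 8, byrow = TRUE)
  expect_equal(P, ref, tolerance = 1e-9)
  props <- deltarad:::glcm_stats(P)
  out2 <- out[65:68]
  expect_equal(unname(props["contrast"]), out2[1], tolerance = 1e-6)
  expect_equal(unname(props["dissimilarity"]), out2[2], tolerance = 1e-6)
  expect_equal(unname(sqrt(props["joint_energy"])), out2[3],
               tolerance = 1e-6)
  expect_equal(unname(props["correlation"]), out2[4], tolerance = 1e-6)
})

test_that("run-length features match hand counting on a tiny strip", {
  # levels along x: 1 1 2 2 2 -> runs in +x: (1,len2), (2,len3)
  vol <- array(c(1, 1, 2, 2, 2), c(5, 1, 1))
  mask <- array(TRUE, c(5, 1, 1))
  la <- deltarad:::levels_array(vol, mask, discretization_params(n_bins = 2))
  counts <- deltarad:::cpp_glrlm_counts(la$levels, dim(la$levels),
                                        matrix(c(1L, 0L, 0L), 1), 2L, 5L)
  r <- counts[, , 1]
  expect_equal(r[1, 2], 1)  # level 1, length 2
  expect_equal(r[2, 3], 1)  # level 2, length 3
  expect_equal(sum(r), 2)
  # SRE / LRE by hand: (1/4 + 1/9)/2 and (4 + 9)/2
  ns <- 2
  expect_equal(sum(r / outer(rep(1, 2), (1:5)^2)) / ns, (1 / 4 + 1 / 9) / 2)
})

test_that("vectorized all-direction GLCM equals the per-matrix reference", {
  set.seed(41)
  for (rep in 1:5) {
    tv <- toy_volume_mask(seed = 40 + rep)
    la <- deltarad:::levels_array(tv$volume, tv$mask,
                                  discretization_params(n_bins = 8))
    counts <- deltarad:::cpp_glcm_counts(la$levels, dim(la$levels),
                                         deltarad:::DIRECTIONS_13, 8L)
    M <- matrix(counts, 64, 13)
    tot <- colSums(M)
    P <- sweep(M, 2, tot, `/`)
    multi <- deltarad:::glcm_stats_multi(P, 8L)
    for (d in c(1, 5, 13)) {
      single <- deltarad:::glcm_stats(matrix(P[, d], 8, 8))
      expect_equal(unname(multi[, d]), unname(single), tolerance = 1e-12)
      expect_identical(rownames(multi), names(single))
    }
  }
})

test_that("texture features are invariant to whole-voxel translation", {
  tv <- toy_volume_mask(seed = 13)
  sh <- function(a, by) {
    out <- array(0, dim(a))
    d <- dim(a)
    out[(1 + by):d[1], , ] <- a[1:(d[1] - by), , ]
    out
  }
  v2 <- sh(tv$volume, 2)
  m2 <- sh(tv$mask, 2) != 0
  g1 <- glcm_features(tv$volume, tv$mask)
  g2 <- glcm_features(v2, m2)
  expect_equal(g1, g2, tolerance = 1e-12)
  expect_equal(glrlm_features(tv$volume, tv$mask), glrlm_features(v2, m2),
               tolerance = 1e-12)
})
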