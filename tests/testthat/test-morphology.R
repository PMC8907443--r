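test_that("voxel-face surface is exact on axis-aligned solids", {
  sv <- array(FALSE, c(3, 3, 3)); sv[2, 2, 2] <- TRUE
  m <- morphology_features(sv, c(1, 1, 1), surface = "voxel_face")
  expect_equal(unname(m["morph_volume"]), 1)
  expect_equal(unname(m["morph_surface_area"]), 6)
  expect_equal(unname(m["morph_av_ratio"]), 6)

  for (L in c(3, 4, 7)) {
    mc <- morphology_features(digitize_cube(L), c(1, 1, 1),
                              surface = "voxel_face")
    expect_equal(unname(mc["morph_av_ratio"]), 6 / L)
    expect_equal(unname(mc["morph_volume"]), L^3)
  }
  # anisotropic spacing: cuboid of a x b x c mm
  box <- array(FALSE, c(6, 6, 6)); box[2:5, 2:4, 2:3] <- TRUE
  sp <- c(0.5, 1, 2)
  ext <- c(4, 3, 2) * sp
  mb <- morphology_features(box, sp, surface = "voxel_face")
  expect_equal(unname(mb["morph_volume"]), prod(ext))
  expect_equal(unname(mb["morph_surface_area"]),
               2 * (ext[1] * ext[2] + ext[1] * ext[3] + ext[2] * ext[3]))
})

test_that("mesh AV of a digitized ball approaches 3/r and converges", {
  errs <- vapply(c(2, 1, 0.5), function(sp) {
    m <- morphology_features(digitize_ball(10, sp), rep(sp, 3))
    av <- unname(m["morph_av_ratio"])
    vol_err <- unname(m["morph_volume"]) / (4 / 3 * pi * 1000) - 1
    expect_lt(abs(vol_err), 0.05)
    abs(av - 0.3) / 0.3
  }, numeric(1))
  expect_lt(errs[2], 0.08)           # within 8% at 1 mm
  expect_true(all(diff(errs) < 0))   # monotone error decay 2 -> 1 -> 0.5 mm
})

test_that("shape descriptors of the ball behave like a sphere's", {
  m <- morphology_features(digitize_ball(10, 1), c(1, 1, 1))
  expect_gt(unname(m["morph_sphericity"]), 0.95)
  expect_lt(unname(m["morph_sphericity"]), 1.05)
  expect_equal(unname(m["morph_max_diameter_3d"]), 20, tolerance = 0.1)
  expect_equal(unname(m["morph_elongation"]), 1, tolerance = 0.05)
  expect_equal(unname(m["morph_flatness"]), 1, tolerance = 0.05)
  expect_equal(unname(m["morph_equivalent_diameter"]),
               2 * (3 * unname(m["morph_volume"]) / (4 * pi))^(1 / 3))
})

test_that("morphology is translation invariant and volume is additive", {
  base <- array(FALSE, c(20, 20, 20))
  base[3:7, 4:9, 5:8] <- TRUE
  base[8, 6, 6] <- TRUE
  shifted <- array(FALSE, c(20, 20, 20))
  shifted[(3:7) + 5, (4:9) + 3, (5:8) + 7] <- TRUE
  shifted[8 + 5, 6 + 3, 6 + 7] <- TRUE
  sp <- c(1.5, 1.5, 1.5)
  expect_equal(morphology_features(base, sp),
               morphology_features(shifted, sp), tolerance = 1e-12)

  two <- base | shifted  # disjoint by construction
  expect_true(!any(base & shifted))
  expect_equal(unname(morphology_features(two, sp)["morph_volume"]),
               unname(morphology_features(base, sp)["morph_volume"]) +
                 unname(morphology_features(shifted, sp)["morph_volume"]))
})

test_that("degenerate masks are flagged, not fatal", {
  sv <- array(FALSE, c(3, 3, 3)); sv[2, 2, 2] <- TRUE
  m <- morphology_features(sv, c(1, 1, 1))
  expect_true(is.na(m["morph_elongation"]))
  expect_gt(unname(m["morph_surface_area"]), 0)  # binary-mesh fallback
  expect_error(morphology_features(array(FALSE, c(3, 3, 3)), c(1, 1, 1)),
               "empty")
})

test_that("mesh surface area agrees with an independent reference mesher", {
  # skimage marching_cubes + mesh_surface_area on the same binary ball;
  # both approximate the analytic sphere, so compare through it
  mask <- digitize_ball(8, 1)
  ours <- mesh_surface_area(mask, c(1, 1, 1))
  f <- tempfile(fileext = ".txt")
  writeLines(as.character(as.integer(mask)), f)
  out <- system2("python", c("-c", shQuote(sprintf("
import numpy as np
from skimage import measure
m = np.loadtxt('%s').reshape((%d, %d, %d), order='F')
v, fcs, _, _ = measure.marching_cubes(m, 0.5)
print(measure.mesh_surface_area(v, fcs))
", f, dim(mask)[1], dim(mask)[2], dim(mask)[3]))), stdout = TRUE)
  ref <- as.numeric(out[length(out)])
  analytic <- 4 * pi * 64
  # each mesher is within 8% of the analytic sphere; their mutual gap is
  # bounded by the sum of the two biases
  expect_lt(abs(ours / analytic - 1), 0.08)
  expect_lt(abs(ref / analytic - 1), 0.08)
  expect_lt(abs(ours / ref - 1), 0.16)
})
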