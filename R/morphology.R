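# Morphological (shape) features of a binary GTV mask.

# Separable binomial smoothing ([1,4,6,4,1]/16 per axis, i.e. two [1,2,1]/4
# passes) of a zero-padded copy of the mask. Restores sub-voxel iso
# crossings so the marching-tetrahedra area of digitized solids converges
# monotonically with finer spacing.
smooth_mask3 <- function(mask, pad = 3L, passes = 2L) {
  d <- dim(mask) + 2L * pad
  a <- array(0, d)
  a[(pad + 1):(d[1] - pad), (pad + 1):(d[2] - pad),
    (pad + 1):(d[3] - pad)] <- as.numeric(mask)
  shift0 <- function(x, ax, by) {
    out <- array(0, dim(x))
    n <- dim(x)[ax]
    src <- seq_len(n) - by
    ok <- src >= 1 & src <= n
    idx_to <- lapply(dim(x), seq_len)
    idx_from <- idx_to
    idx_to[[ax]] <- which(ok)
    idx_from[[ax]] <- src[ok]
    out[idx_to[[1]], idx_to[[2]], idx_to[[3]]] <-
      x[idx_from[[1]], idx_from[[2]], idx_from[[3]]]
    out
  }
  for (p in seq_len(passes)) for (ax in 1:3)
    a <- 0.25 * shift0(a, ax, -1L) + 0.5 * a + 0.25 * shift0(a, ax, 1L)
  a
}

# Crop a mask to its bounding box (callers pad as needed).
crop_mask <- function(mask) {
  d <- dim(mask)
  idx <- which(mask != 0) - 1L
  ix <- idx %% d[1]
  iy <- (idx %/% d[1]) %% d[2]
  iz <- idx %/% (d[1] * d[2])
  mask[(min(ix) + 1L):(max(ix) + 1L),
       (min(iy) + 1L):(max(iy) + 1L),
       (min(iz) + 1L):(max(iz) + 1L), drop = FALSE]
}

#' Mesh surface area of a binary mask
#'
#' Marching-tetrahedra triangulation at iso level 0.5 of a binomially
#' smoothed copy of the mask (sub-voxel crossings by linear interpolation).
#' For masks so small that smoothing erases them (a few voxels), the
#' unsmoothed binary field is meshed instead.
#'
#' @param mask 3D binary array.
#' @param spacing Voxel spacing in mm.
#' @return Surface area in mm^2.
#' @export
mesh_surface_area <- function(mask, spacing) {
  # crop to the mask bounding box (the smoothing pad restores closure)
  mask <- crop_mask(mask)
  sm <- smooth_mask3(mask)
  a <- cpp_mesh_area(as.numeric(sm), dim(sm), as.numeric(spacing), 0.5)
  if (a <= 0) {
    d <- dim(mask) + 2L
    f <- array(0, d)
    f[2:(d[1] - 1), 2:(d[2] - 1), 2:(d[3] - 1)] <- as.numeric(mask)
    a <- cpp_mesh_area(as.numeric(f), d, as.numeric(spacing), 0.5)
  }
  a
}

# Exposed-face surface area; exact on axis-aligned solids, test-only
# companion of the mesh estimate.
voxel_face_area <- function(mask, spacing) {
  d <- dim(mask)
  m <- array(FALSE, d + 2L)
  m[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- mask != 0
  face <- c(spacing[2] * spacing[3], spacing[1] * spacing[3],
            spacing[1] * spacing[2])
  total <- 0
  for (ax in 1:3) {
    n <- dim(m)[ax]
    idx <- lapply(dim(m), seq_len)
    lo <- idx; lo[[ax]] <- 1:(n - 1)
    hi <- idx; hi[[ax]] <- 2:n
    diffm <- m[lo[[1]], lo[[2]], lo[[3]]] != m[hi[[1]], hi[[2]], hi[[3]]]
    total <- total + sum(diffm) * face[ax]
  }
  total
}

# Exact pruning for the maximum-diameter search: any point extremal in
# some direction n is the min or max along the axis most aligned with n on
# its grid line, so the per-line axis extremes contain both endpoints of
# the farthest pair.
extremal_voxels <- function(idx) {
  if (nrow(idx) < 3) return(idx)
  sel <- logical(nrow(idx))
  for (ax in 1:3) {
    others <- setdiff(1:3, ax)
    key <- idx[, others[1]] * 1e6 + idx[, others[2]]
    o <- order(key, idx[, ax])
    k <- key[o]
    sel[o[!duplicated(k)]] <- TRUE
    sel[o[!duplicated(k, fromLast = TRUE)]] <- TRUE
  }
  idx[sel, , drop = FALSE]
}

# Boundary ROI voxels: inside the mask with at least one 6-neighbour
# outside (array edges count as outside).
boundary_voxels <- function(mask) {
  d <- dim(mask)
  m <- array(FALSE, d + 2L)
  m[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- mask != 0
  core <- m[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)]
  inner <- core
  inner <- inner & m[1:d[1], 2:(d[2] + 1), 2:(d[3] + 1)]
  inner <- inner & m[3:(d[1] + 2), 2:(d[2] + 1), 2:(d[3] + 1)]
  inner <- inner & m[2:(d[1] + 1), 1:d[2], 2:(d[3] + 1)]
  inner <- inner & m[2:(d[1] + 1), 3:(d[2] + 2), 2:(d[3] + 1)]
  inner <- inner & m[2:(d[1] + 1), 2:(d[2] + 1), 1:d[3]]
  inner <- inner & m[2:(d[1] + 1), 2:(d[2] + 1), 3:(d[3] + 2)]
  array(core & !inner, d)   # restore dims dropped by degenerate subsets
}

#' Morphological features of a GTV mask
#'
#' Volume (voxel count times voxel volume), mesh surface area, the
#' surface-to-volume ratio AV (mm^-1), sphericity and related compactness
#' measures, maximum 3D diameter, and principal-axis lengths with
#' elongation and flatness. Axis-derived features of degenerate (flat or
#' single-voxel) masks are returned as `NA` (undefined by convention).
#'
#' @param mask 3D binary array, nonempty.
#' @param spacing Voxel spacing in mm.
#' @param surface `"mesh"` (default) or `"voxel_face"` (exact on
#'   axis-aligned solids; test-oriented).
#' @return Named numeric vector over the 15 morphological catalog features.
#' @export
morphology_features <- function(mask, spacing,
                                surface = c("mesh", "voxel_face")) {
  surface <- match.arg(surface)
  mask <- mask != 0
  nvox <- sum(mask)
  if (nvox == 0) stop("empty mask")
  mask <- crop_mask(mask)   # every feature below is translation-invariant
  voxvol <- prod(spacing)
  V <- nvox * voxvol
  A <- if (surface == "mesh") mesh_surface_area(mask, spacing)
       else voxel_face_area(mask, spacing)

  R <- (3 * V / (4 * pi))^(1 / 3)
  sphericity <- (pi^(1 / 3) * (6 * V)^(2 / 3)) / A
  compact1 <- V / (sqrt(pi) * A^1.5)
  compact2 <- 36 * pi * V^2 / A^3
  sph_disp <- A / (4 * pi * R^2)

  idx <- which(mask, arr.ind = TRUE)
  pts <- sweep(idx - 1, 2, spacing, `*`)
  bvox <- which(boundary_voxels(mask), arr.ind = TRUE)
  bvox <- extremal_voxels(bvox)
  bpts <- sweep(bvox - 1, 2, spacing, `*`)
  maxdiam <- if (nrow(bpts) >= 2) cpp_max_pairwise_dist(bpts) else 0

  if (nvox >= 2) {
    cv <- crossprod(sweep(pts, 2, colMeans(pts))) / nvox
    ev <- sort(eigen(cv, symmetric = TRUE, only.values = TRUE)$values,
               decreasing = TRUE)
    ev <- pmax(ev, 0)
    axes <- 4 * sqrt(ev)
    elong <- if (ev[1] > 0) sqrt(ev[2] / ev[1]) else NA_real_
    flat <- if (ev[1] > 0) sqrt(ev[3] / ev[1]) else NA_real_
  } else {
    axes <- c(NA_real_, NA_real_, NA_real_)
    elong <- NA_real_
    flat <- NA_real_
  }
  bbox <- apply(idx, 2, range)
  bbox_mm <- (bbox[2, ] - bbox[1, ] + 1) * spacing
  extent <- V / prod(bbox_mm)

  out <- c(V, A, A / V, sphericity, compact1, compact2, sph_disp, 2 * R,
           maxdiam, axes[1], axes[2], axes[3], elong, flat, extent)
  names(out) <- MORPH_NAMES
  out
}
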