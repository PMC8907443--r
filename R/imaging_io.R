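#' Patient imaging series
#'
#' One patient's co-registered longitudinal series: one MR volume and one
#' GTV mask per timepoint, aligned to a cumulative BED level per timepoint
#' (first entry 0 = simulation scan).
#'
#' @param patient_id Character scalar.
#' @param volumes List of 3D numeric arrays (may be `NULL` for a masks-only
#'   series, e.g. morphology-only workflows).
#' @param masks List of 3D binary arrays, one per timepoint, all nonempty.
#' @param bed_levels Numeric vector of cumulative BED (Gy), strictly
#'   increasing, starting at 0.
#' @param spacing Voxel spacing in mm (length 3, > 0).
#' @return Object of class `patient_series`.
#' @export
patient_series <- function(patient_id, volumes, masks, bed_levels, spacing) {
  stopifnot(length(spacing) == 3, all(spacing > 0))
  nt <- length(masks)
  if (nt < 2) stop("a series needs at least two timepoints")
  if (length(bed_levels) != nt)
    stop("bed_levels length must match the number of timepoints")
  if (bed_levels[1] != 0)
    stop("no BED=0 timepoint: the first timepoint must be the simulation scan")
  if (any(diff(bed_levels) <= 0))
    stop("bed_levels must be strictly increasing")
  if (!is.null(volumes) && length(volumes) != nt)
    stop("volumes and masks must have the same length")
  d0 <- dim(masks[[1]])
  for (t in seq_len(nt)) {
    m <- masks[[t]]
    if (!identical(dim(m), d0))
      stop("mask shape mismatch at timepoint ", t)
    if (!any(m != 0)) stop("empty mask at timepoint ", t)
    masks[[t]] <- (m != 0)
    if (!is.null(volumes) && !identical(dim(volumes[[t]]), d0))
      stop("image/mask shape mismatch at timepoint ", t)
  }
  structure(list(patient_id = as.character(patient_id), volumes = volumes,
                 masks = masks, bed_levels = as.numeric(bed_levels),
                 spacing = as.numeric(spacing)),
            class = "patient_series")
}

#' @export
print.patient_series <- function(x, ...) {
  cat(sprintf("patient_series %s: %d timepoints, BED %s Gy, %s voxels @ %s mm\n",
              x$patient_id, length(x$masks),
              paste(round(x$bed_levels, 1), collapse = "/"),
              paste(dim(x$masks[[1]]), collapse = "x"),
              paste(x$spacing, collapse = "x")))
  invisible(x)
}

#' Write a cohort of series as NIfTI files plus a manifest
#'
#' Writes `<id>_t<k>_img.nii.gz` / `<id>_t<k>_mask.nii.gz` per timepoint
#' under `dir` and a `manifest.csv` with columns `patient_id`,
#' `timepoint`, `bed_gy`, `image_path`, `mask_path` (paths relative to the
#' manifest location). Masks-only series write an empty `image_path`.
#'
#' @param series_list List of [patient_series()].
#' @param dir Output directory (created if needed).
#' @return Path of the written manifest, invisibly.
#' @export
write_cohort_images <- function(series_list, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (s in series_list) {
    stopifnot(inherits(s, "patient_series"))
    for (t in seq_along(s$masks)) {
      img_rel <- ""
      if (!is.null(s$volumes)) {
        img_rel <- sprintf("%s_t%d_img.nii.gz", s$patient_id, t)
        nifti_write(s$volumes[[t]], file.path(dir, img_rel), s$spacing)
      }
      msk_rel <- sprintf("%s_t%d_mask.nii.gz", s$patient_id, t)
      nifti_write(s$masks[[t]], file.path(dir, msk_rel), s$spacing)
      rows[[length(rows) + 1L]] <- data.frame(
        patient_id = s$patient_id, timepoint = t, bed_gy = s$bed_levels[t],
        image_path = img_rel, mask_path = msk_rel,
        stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  path <- file.path(dir, "manifest.csv")
  write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}

#' Read and validate a cohort manifest
#'
#' @param path Path to a `manifest.csv` written by [write_cohort_images()]
#'   (or with the same columns).
#' @return Data frame with an attribute `base_dir` used to resolve the
#'   relative image/mask paths.
#' @export
read_manifest <- function(path) {
  m <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "timepoint", "bed_gy", "image_path", "mask_path")
  if (!all(need %in% names(m)))
    stop("manifest is missing columns: ",
         paste(setdiff(need, names(m)), collapse = ", "))
  m$image_path[is.na(m$image_path)] <- ""   # masks-only rows
  if (anyDuplicated(m[c("patient_id", "timepoint")]))
    stop("duplicate (patient_id, timepoint) rows in manifest")
  bad <- tapply(m$bed_gy, m$patient_id, function(b) !any(b == 0))
  if (any(bad))
    stop("no BED=0 timepoint for patient(s): ",
         paste(names(bad)[bad], collapse = ", "))
  attr(m, "base_dir") <- dirname(normalizePath(path))
  m
}

#' Load one patient's series from a manifest
#'
#' Timepoints are sorted by BED; masks are binarized (any nonzero voxel is
#' ROI); image/mask geometry is validated per timepoint.
#'
#' @param manifest Data frame from [read_manifest()].
#' @param patient_id Patient to load.
#' @return A [patient_series()].
#' @export
load_series <- function(manifest, patient_id) {
  base <- attr(manifest, "base_dir")
  if (is.null(base)) base <- "."
  rows <- manifest[manifest$patient_id == patient_id, , drop = FALSE]
  if (!nrow(rows)) stop("patient not in manifest: ", patient_id)
  rows <- rows[order(rows$bed_gy), , drop = FALSE]
  volumes <- list()
  masks <- list()
  spacing <- NULL
  has_images <- any(nzchar(rows$image_path))
  for (i in seq_len(nrow(rows))) {
    mk <- nifti_read(file.path(base, rows$mask_path[i]))
    if (is.null(spacing)) spacing <- mk$spacing
    if (has_images) {
      im <- nifti_read(file.path(base, rows$image_path[i]))
      if (!identical(dim(im$data), dim(mk$data)))
        stop("image/mask shape mismatch at timepoint ", rows$timepoint[i],
             " of patient ", patient_id)
      if (max(abs(im$spacing - mk$spacing)) > 1e-4)
        stop("image/mask spacing mismatch at timepoint ", rows$timepoint[i],
             " of patient ", patient_id)
      volumes[[i]] <- im$data
    }
    if (!any(mk$data != 0))
      stop("empty mask at timepoint ", rows$timepoint[i],
           " of patient ", patient_id)
    masks[[i]] <- mk$data != 0
  }
  patient_series(patient_id, if (has_images) volumes else NULL, masks,
                 rows$bed_gy, spacing)
}
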