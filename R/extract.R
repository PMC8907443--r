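# Catalog extraction over a patient series.

#' Extract the full feature catalog for one (image, mask) pair
#'
#' @param volume 3D numeric array, or `NULL` for a masks-only extraction
#'   (intensity features are returned as `NA`).
#' @param mask 3D binary array.
#' @param spacing Voxel spacing in mm.
#' @param catalog A [feature_catalog()].
#' @param norm A [normalization_params()] applied to `volume` before the
#'   intensity families.
#' @param disc A [discretization_params()].
#' @return Named numeric vector over the catalog; undefined-by-convention
#'   values are `NA`.
#' @export
extract_features <- function(volume, mask, spacing,
                             catalog = feature_catalog(),
                             norm = normalization_params(),
                             disc = discretization_params()) {
  out <- rep(NA_real_, nrow(catalog))
  names(out) <- catalog$name
  morph <- morphology_features(mask, spacing)
  out[names(morph)] <- morph
  if (!is.null(volume)) {
    vol <- normalize_volume(volume, norm, mask)
    fo <- firstorder_features(vol, mask, disc, voxel_volume = prod(spacing))
    out[names(fo)] <- fo
    dists <- unique(as.integer(sub(".*_d(\\d+)$", "\\1",
                                   grep("^glcm_", catalog$name,
                                        value = TRUE))))
    if (length(dists) && sum(mask != 0) >= 2) {
      gl <- glcm_features(vol, mask, disc, distances = sort(dists))
      out[intersect(names(gl), names(out))] <-
        gl[intersect(names(gl), names(out))]
    }
    if (any(grepl("^glrlm_", catalog$name))) {
      rl <- glrlm_features(vol, mask, disc)
      out[names(rl)] <- rl
    }
  }
  out
}

#' Extract the catalog at every timepoint of a series
#'
#' @param series A [patient_series()].
#' @inheritParams extract_features
#' @return Object of class `feature_vectors`: list with `features`
#'   (timepoints x catalog matrix), `bed_levels`, `patient_id` and the
#'   extraction provenance.
#' @export
extract_catalog <- function(series, catalog = feature_catalog(),
                            norm = normalization_params(),
                            disc = discretization_params()) {
  stopifnot(inherits(series, "patient_series"))
  nt <- length(series$masks)
  mat <- matrix(NA_real_, nt, nrow(catalog),
                dimnames = list(NULL, catalog$name))
  for (t in seq_len(nt)) {
    vol <- if (is.null(series$volumes)) NULL else series$volumes[[t]]
    mat[t, ] <- extract_features(vol, series$masks[[t]], series$spacing,
                                 catalog, norm, disc)
  }
  structure(list(patient_id = series$patient_id, features = mat,
                 bed_levels = series$bed_levels,
                 provenance = list(norm = norm, disc = disc,
                                   catalog_size = nrow(catalog))),
            class = "feature_vectors")
}

#' Basal feature table for a whole cohort
#'
#' One row per patient; columns `<feature>@bed<level>` for every catalog
#' feature at every timepoint (582 columns for the default 97-feature
#' catalog over 6 timepoints). BED levels in column names are rounded to
#' the nearest Gy for readability.
#'
#' @param series_list List of [patient_series()], or a `mrgrt_cohort`.
#' @inheritParams extract_features
#' @return Data frame of basal features with a `patient_id` column.
#' @export
extract_cohort_features <- function(series_list,
                                    catalog = feature_catalog(),
                                    norm = normalization_params(),
                                    disc = discretization_params()) {
  if (inherits(series_list, "mrgrt_cohort")) series_list <- series_list$series
  rows <- lapply(series_list, function(s) {
    fv <- extract_catalog(s, catalog, norm, disc)
    vals <- as.vector(t(fv$features))
    names(vals) <- as.vector(vapply(round(fv$bed_levels), function(b)
      paste0(colnames(fv$features), "@bed", b), character(ncol(fv$features))))
    c(list(patient_id = s$patient_id), as.list(vals))
  })
  do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, check.names = FALSE, stringsAsFactors = FALSE)))
}

#' Tidy (long) view of a wide basal feature table
#'
#' @param basal Wide table from [extract_cohort_features()].
#' @return Data frame with columns `patient_id`, `bed_gy`, `feature`,
#'   `value`.
#' @export
tidy_features <- function(basal) {
  cols <- setdiff(names(basal), "patient_id")
  data.frame(
    patient_id = rep(basal$patient_id, each = length(cols)),
    bed_gy = rep(as.integer(sub(".*@bed(\\d+)$", "\\1", cols)),
                 nrow(basal)),
    feature = rep(sub("@bed\\d+$", "", cols), nrow(basal)),
    value = as.vector(t(as.matrix(basal[cols]))),
    stringsAsFactors = FALSE)
}

#' Serialize / restore a feature catalog manifest
#'
#' @param catalog A [feature_catalog()].
#' @param path JSON file path.
#' @return `path` (write) or the catalog (read).
#' @export
write_feature_catalog <- function(catalog, path) {
  jsonlite::write_json(list(version = 1L, size = nrow(catalog),
                            features = as.data.frame(catalog)),
                       path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_feature_catalog
#' @export
read_feature_catalog <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cat <- obj$features
  stopifnot(identical(nrow(cat), as.integer(obj$size)),
            !anyDuplicated(cat$name))
  class(cat) <- c("feature_catalog", "data.frame")
  cat
}
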