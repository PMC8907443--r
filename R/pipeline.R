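# End-to-end pipeline orchestration with a JSON config.

#' Default pipeline configuration
#'
#' @param out_dir Output directory for all stage artifacts.
#' @param seed Master seed.
#' @return Nested configuration list (class `pipeline_config`).
#' @export
default_pipeline_config <- function(out_dir = "deltarad_run", seed = 1L) {
  structure(list(
    cohort = list(n_patients = 10L, event_prevalence = 1 / 6,
                  effect_size = 4.5, n_timepoints = 6L,
                  voxel_spacing = c(1.5, 1.5, 1.5),
                  image_shape = c(48L, 48L, 48L), noise_sd = 5),
    preprocessing = list(method = "zscore",
                         reference_region = "whole_volume"),
    radiomics = list(n_bins = 32L, glcm_distances = c(1L, 2L)),
    stats = list(alpha = 0.05, n_boot = 2000L,
                 chemo_var = "chemo_with_oxa"),
    seed = as.integer(seed), out_dir = out_dir),
    class = "pipeline_config")
}

#' Read / write a pipeline configuration
#'
#' @param path JSON file path.
#' @param config Configuration list.
#' @return The configuration (read) or `path` (write, invisibly).
#' @export
read_pipeline_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  base <- default_pipeline_config()
  for (blk in names(cfg)) {
    if (is.list(base[[blk]])) {
      for (k in names(cfg[[blk]])) base[[blk]][[k]] <- cfg[[blk]][[k]]
    } else base[[blk]] <- cfg[[blk]]
  }
  base
}

#' @rdname read_pipeline_config
#' @export
write_pipeline_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(path)
}

config_hash <- function(config) {
  s <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA)
  # small stable polynomial hash in double arithmetic (exact below 2^53)
  h <- 5381
  for (b in utf8ToInt(as.character(s))) h <- (h * 33 + b) %% 4294967291
  sprintf("%08x", as.integer(h %% 2147483647))
}

pipeline_paths <- function(config) {
  d <- config$out_dir
  list(dir = d, images = file.path(d, "images"),
       manifest = file.path(d, "images", "manifest.csv"),
       clinical = file.path(d, "clinical.csv"),
       basal = file.path(d, "basal_features.csv"),
       delta = file.path(d, "delta_features.csv"),
       screening = file.path(d, "screening.csv"),
       report = file.path(d, "report.csv"),
       models = file.path(d, "models.json"),
       run_info = file.path(d, "run_info.json"))
}

need_artifact <- function(path, produced_by) {
  if (!file.exists(path))
    stop("missing artifact ", path, "; run stage '", produced_by,
         "' first", call. = FALSE)
  path
}

#' Delta features from a wide basal table
#'
#' Table-level counterpart of [delta_features()]: given a wide basal
#' feature table (columns `<feature>@bed<level>`, one row per patient),
#' computes every `<feature>(d<k>)` ratio against the BED-0 columns.
#'
#' @param basal Data frame with a `patient_id` column and
#'   `<feature>@bed<level>` columns.
#' @param tol Baseline magnitude below which a ratio is flagged `NA`.
#' @return Data frame of delta features with a `patient_id` column.
#' @export
delta_from_basal <- function(basal, tol = 1e-8) {
  cols <- setdiff(names(basal), "patient_id")
  feat <- sub("@bed\\d+$", "", cols)
  bed <- as.integer(sub(".*@bed(\\d+)$", "\\1", cols))
  beds <- sort(unique(bed))
  if (beds[1] != 0) stop("no BED=0 columns in basal table")
  out <- data.frame(patient_id = basal$patient_id, stringsAsFactors = FALSE)
  for (k in seq_along(beds[-1])) {
    L <- beds[k + 1]
    for (f in unique(feat)) {
      b0 <- basal[[paste0(f, "@bed0")]]
      bk <- basal[[paste0(f, "@bed", L)]]
      out[[paste0(f, "(d", k, ")")]] <- ifelse(abs(b0) < tol, NA_real_,
                                               bk / b0)
    }
  }
  out
}

#' Run pipeline stages
#'
#' Stages: `simulate` (synthetic cohort to NIfTI + manifest + clinical
#' CSV), `extract` (basal features), `delta`, `screen`, `fit` (models +
#' report) and `all` (the whole chain). Downstream stages error with the
#' name of the stage to run first when an upstream artifact is missing.
#' Every run writes `run_info.json` with the config hash.
#'
#' @param stage One of `"simulate"`, `"extract"`, `"delta"`, `"screen"`,
#'   `"fit"` (alias `"report"`), `"all"`.
#' @param config A `pipeline_config` (see [default_pipeline_config()]) or
#'   a path to a JSON config.
#' @return Invisible list of artifact paths written.
#' @export
run_pipeline <- function(stage = c("all", "simulate", "extract", "delta",
                                   "screen", "fit", "report"),
                         config = default_pipeline_config()) {
  stage <- match.arg(stage)
  if (is.character(config)) config <- read_pipeline_config(config)
  p <- pipeline_paths(config)
  dir.create(p$dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  log_stage <- function(name, t0, detail) {
    message(sprintf("[deltarad] %-8s %5.1fs  %s", name,
                    as.numeric(Sys.time()) - t0, detail))
  }

  if (stage %in% c("simulate", "all")) {
    t0 <- as.numeric(Sys.time())
    cc <- do.call(cohort_config, c(config$cohort,
                                   list(rng_seed = config$seed)))
    cohort <- simulate_cohort(cc)
    write_cohort_images(cohort$series, p$images)
    write.csv(cohort$clinical, p$clinical, row.names = FALSE)
    written <- c(written, p$manifest, p$clinical)
    log_stage("simulate", t0, sprintf("%d patients, %d events",
                                      cc$n_patients,
                                      sum(cohort$clinical$dfs2y == 0)))
  }
  if (stage %in% c("extract", "all")) {
    t0 <- as.numeric(Sys.time())
    manifest <- read_manifest(need_artifact(p$manifest, "simulate"))
    norm <- normalization_params(config$preprocessing$method,
                                 config$preprocessing$reference_region)
    disc <- discretization_params(n_bins = config$radiomics$n_bins)
    catalog <- feature_catalog(config$radiomics$glcm_distances)
    ids <- unique(manifest$patient_id)
    basal <- do.call(rbind, lapply(ids, function(id)
      extract_cohort_features(list(load_series(manifest, id)), catalog,
                              norm, disc)))
    write.csv(basal, p$basal, row.names = FALSE)
    written <- c(written, p$basal)
    log_stage("extract", t0, sprintf("%d patients x %d basal features",
                                     nrow(basal), ncol(basal) - 1L))
  }
  if (stage %in% c("delta", "all")) {
    t0 <- as.numeric(Sys.time())
    basal <- read.csv(need_artifact(p$basal, "extract"),
                      check.names = FALSE)
    delta <- delta_from_basal(basal)
    write.csv(delta, p$delta, row.names = FALSE)
    written <- c(written, p$delta)
    log_stage("delta", t0, sprintf("%d delta features", ncol(delta) - 1L))
  }
  if (stage %in% c("screen", "all")) {
    t0 <- as.numeric(Sys.time())
    basal <- read.csv(need_artifact(p$basal, "extract"),
                      check.names = FALSE)
    delta <- read.csv(need_artifact(p$delta, "delta"), check.names = FALSE)
    clinical <- read.csv(need_artifact(p$clinical, "simulate"))
    tab <- assemble_variable_table(basal, delta, clinical_design(clinical))
    sr <- screen_features(tab, alpha = config$stats$alpha)
    write.csv(sr$table, p$screening, row.names = FALSE)
    written <- c(written, p$screening)
    log_stage("screen", t0,
              sprintf("%d tested, %d significant", sr$n_tested,
                      sum(sr$table$significant, na.rm = TRUE)))
  }
  if (stage %in% c("fit", "report", "all")) {
    t0 <- as.numeric(Sys.time())
    basal <- read.csv(need_artifact(p$basal, "extract"),
                      check.names = FALSE)
    delta <- read.csv(need_artifact(p$delta, "delta"), check.names = FALSE)
    clinical <- read.csv(need_artifact(p$clinical, "simulate"))
    tab <- assemble_variable_table(basal, delta, clinical_design(clinical))
    set.seed(child_seed(config$seed, 0L, 9L))
    ms <- build_models(tab, chemo_var = config$stats$chemo_var,
                       alpha = config$stats$alpha,
                       n_boot = config$stats$n_boot)
    write.csv(ms$table2, p$report, row.names = FALSE)
    jsonlite::write_json(
      list(config_hash = config_hash(config),
           best_feature = ms$best_feature,
           models = lapply(ms$models, function(m)
             list(auc = m$auc, ci = m$auc_ci, threshold = m$threshold,
                  sensitivity = m$sensitivity,
                  specificity = m$specificity, j_index = m$j_index,
                  coefficients = as.list(m$fit$coefficients),
                  penalized = m$fit$penalized))),
      p$models, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    written <- c(written, p$report, p$models)
    log_stage("fit", t0, sprintf("best feature %s", ms$best_feature))
  }
  jsonlite::write_json(list(config_hash = config_hash(config),
                            stage = stage, seed = config$seed,
                            written = written),
                       p$run_info, auto_unbox = TRUE, pretty = TRUE)
  invisible(written)
}

#' Command-line entry point
#'
#' Thin wrapper so the pipeline can be driven as
#' `Rscript -e 'deltarad::main()' <stage> --config cfg.json
#' [--seed N] [--out DIR]` (also installed as `inst/cli/deltarad`).
#'
#' @param args Character vector of CLI arguments (defaults to
#'   `commandArgs(trailingOnly = TRUE)`).
#' @return Exit status, invisibly.
#' @export
main <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste("usage: deltarad <simulate|extract|delta|screen|fit|all>",
                 "[--config FILE] [--seed N] [--out DIR]")
  if (!length(args)) { message(usage); return(invisible(1L)) }
  stage <- args[1]
  getopt <- function(flag) {
    i <- which(args == flag)
    if (length(i) && i < length(args)) args[i + 1] else NULL
  }
  config <- if (!is.null(getopt("--config")))
    read_pipeline_config(getopt("--config")) else default_pipeline_config()
  if (!is.null(getopt("--seed"))) config$seed <- as.integer(getopt("--seed"))
  if (!is.null(getopt("--out"))) config$out_dir <- getopt("--out")
  run_pipeline(stage, config)
  invisible(0L)
}
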