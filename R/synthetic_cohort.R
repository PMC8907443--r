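# Synthetic MRgRT cohort generator: six-timepoint shrinking, textured
# tumour phantoms with the outcome effect carried by the change in the GTV
# surface-to-volume ratio at the fourth BED level.

#' Cohort generator configuration
#'
#' Defaults describe the emulated study setting: 1.5 mm isotropic low-field
#' MR, six imaging timepoints (simulation plus the 13/26/40/54/67 Gy BED
#' levels of a 2.2 Gy x 25 boost scheme), ~1/6 event prevalence, and an
#' outcome effect of 4.5 log-odds per SD of the standardized delta
#' surface-to-volume ratio at the fourth post-simulation level.
#'
#' @param n_patients Number of patients (>= 2).
#' @param event_prevalence Target event (no-2yDFS) fraction in (0, 1).
#' @param effect_size Log-odds of an event per SD of the embedded
#'   delta-AV predictor (0 = null cohort).
#' @param n_timepoints Timepoints incl. simulation (2..6).
#' @param voxel_spacing Voxel spacing in mm (3 positive values).
#' @param image_shape Grid size in voxels (3 values).
#' @param noise_sd Additive Gaussian intensity noise SD.
#' @param responder_decay List with `mean_range` (patient-level mean
#'   per-timepoint fractional volume loss is uniform on it), `sd`
#'   (within-patient spread) and `max` (per-step cap).
#' @param chemo_effect Log-odds contribution of oxaliplatin-based
#'   chemotherapy to the event probability.
#' @param irregularity List with `gamma` (boundary-irregularity response
#'   per SD of the patient latent) and optional `weights` (per-timepoint
#'   localization, defaults to a profile peaking at the 4th
#'   post-simulation level).
#' @param radius_range Baseline tumour equivalent radius range in mm.
#' @param rng_seed Master seed (integer) or `NULL` to seed at simulate time.
#' @return Object of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 48L, event_prevalence = 1 / 6,
                          effect_size = 4.5, n_timepoints = 6L,
                          voxel_spacing = c(1.5, 1.5, 1.5),
                          image_shape = c(48L, 48L, 48L), noise_sd = 5,
                          responder_decay = list(mean_range = c(0.08, 0.22),
                                                 sd = 0.04, max = 0.45),
                          chemo_effect = 0.9,
                          irregularity = list(gamma = 1.8, weights = NULL),
                          radius_range = c(10, 18), rng_seed = NULL) {
  stopifnot(n_patients >= 2, event_prevalence > 0, event_prevalence < 1,
            n_timepoints >= 2, n_timepoints <= 6,
            length(voxel_spacing) == 3, all(voxel_spacing > 0),
            length(image_shape) == 3, all(image_shape >= 8),
            noise_sd >= 0, diff(radius_range) >= 0)
  if (is.null(irregularity$weights)) {
    # localize boundary irregularity at the 4th post-simulation level
    w6 <- c(0, 0.05, 0.10, 0.15, 1, 0.25)
    irregularity$weights <- w6[seq_len(n_timepoints)]
  }
  stopifnot(length(irregularity$weights) == n_timepoints)
  structure(list(n_patients = as.integer(n_patients),
                 event_prevalence = event_prevalence,
                 effect_size = effect_size,
                 n_timepoints = as.integer(n_timepoints),
                 voxel_spacing = as.numeric(voxel_spacing),
                 image_shape = as.integer(image_shape),
                 noise_sd = noise_sd, responder_decay = responder_decay,
                 chemo_effect = chemo_effect, irregularity = irregularity,
                 radius_range = radius_range, rng_seed = rng_seed),
            class = "cohort_config")
}

#' Tumour volume regression trajectory
#'
#' `volume(t) = v0 * prod_{k <= t} (1 - decay_k)`; non-increasing in `t`.
#'
#' @param v0 Baseline volume (> 0).
#' @param decay Per-timepoint fractional volume losses in `[0, 1)`.
#' @param t Timepoint index (0 = baseline).
#' @return Volume at timepoint `t`.
#' @export
regression_trajectory <- function(v0, decay, t) {
  stopifnot(v0 > 0, all(decay >= 0), all(decay < 1), t >= 0,
            t <= length(decay))
  if (t == 0) return(v0)
  v0 * prod(1 - decay[seq_len(t)])
}

# Rasterize one timepoint of a patient tumour model into the full grid.
rasterize_timepoint <- function(shape, spacing, center, axes, bump_dir,
                                bump_amp, bump_invw2, rip_dir, rip_amp,
                                rip_omega, rip_phase) {
  rmax <- (max(axes) + max(c(bump_amp, 0))) * (1 + sum(abs(rip_amp))) +
    2 * max(spacing)
  lo <- pmax(1L, floor((center - rmax) / spacing) + 1L)
  hi <- pmin(shape, ceiling((center + rmax) / spacing) + 1L)
  sub_dim <- as.integer(hi - lo + 1L)
  origin <- (lo - 1L) * spacing
  sub <- cpp_rasterize_radial(sub_dim, origin, spacing, center,
                              1 / axes^2, bump_dir, bump_amp, bump_invw2,
                              rip_dir, rip_amp, rip_omega, rip_phase)
  mask <- array(FALSE, shape)
  mask[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- array(sub, sub_dim)
  mask
}

# Textured intensity volume: tissue base + tumour contrast + a few random
# cosine waves (spatially correlated texture) + white noise. Consumes the
# current RNG stream.
texture_volume <- function(shape, spacing, mask, noise_sd) {
  xs <- (seq_len(shape[1]) - 1) * spacing[1]
  ys <- (seq_len(shape[2]) - 1) * spacing[2]
  zs <- (seq_len(shape[3]) - 1) * spacing[3]
  vol <- array(60, shape) + 40 * mask
  for (w in 1:3) {
    dir <- rnorm(3)
    dir <- dir / sqrt(sum(dir^2))
    lambda <- runif(1, 6, 15)
    amp <- runif(1, 4, 9)
    phase <- runif(1, 0, 2 * pi)
    phase_arr <- outer(outer(dir[1] * xs, dir[2] * ys, `+`), dir[3] * zs,
                       `+`)
    vol <- vol + amp * cos(2 * pi * phase_arr / lambda + phase)
  }
  if (noise_sd > 0)
    vol <- vol + array(rnorm(prod(shape), 0, noise_sd), shape)
  vol
}

#' Simulate a synthetic MRgRT cohort
#'
#' Each patient gets a baseline lobulated tumour (ellipsoid plus 2-4
#' Gaussian angular bumps) that shrinks along a per-patient decay
#' trajectory; a patient latent modulates boundary irregularity with a
#' per-timepoint weight profile peaking at the 4th post-simulation BED
#' level. Outcome labels are drawn from a logistic model on the measured
#' (digitized-mask) standardized delta surface-to-volume ratio at that
#' level plus an oxaliplatin-chemotherapy indicator, with the intercept
#' solved numerically for the configured prevalence. Per-patient RNG
#' streams are derived from the master seed, so cohorts are extensible
#' without reshuffling, and intensity synthesis uses a separate substream,
#' so `images = FALSE` yields identical masks, geometry and labels.
#'
#' @param config A [cohort_config()].
#' @param seed Master seed; defaults to `config$rng_seed`.
#' @param images Synthesize textured intensity volumes (default TRUE).
#'   `FALSE` gives a masks-only cohort (faster; morphology-only workflows).
#' @param mode `"full"` (default) or `"labels"`: the latter rasterizes only
#'   the two timepoints that determine the outcome and returns no series —
#'   meant for label-calibration studies at large n; clinical table,
#'   latents and outcomes are bit-identical to a full run.
#' @return Object of class `mrgrt_cohort`: list with `series` (list of
#'   [patient_series()]), `clinical` (data frame incl. outcome `dfs2y`),
#'   `geometry` (per patient-timepoint volume/surface/AV table), `latent`
#'   (embedded predictor bookkeeping), `flags`, `config`.
#' @export
simulate_cohort <- function(config = cohort_config(),
                            seed = config$rng_seed, images = TRUE,
                            mode = c("full", "labels")) {
  stopifnot(inherits(config, "cohort_config"))
  mode <- match.arg(mode)
  if (is.null(seed)) stop("no seed: set config$rng_seed or pass seed")
  n <- config$n_patients
  nt <- config$n_timepoints
  k_sig <- min(4L, nt - 1L)
  # labels mode: rasterize and mesh only the two timepoints that determine
  # the outcome (simulation and the signal level); geometry params and all
  # random draws are identical to a full run, so labels match bit for bit
  tp_keep <- if (mode == "labels") c(1L, k_sig + 1L) else seq_len(nt)
  shape <- config$image_shape
  spacing <- config$voxel_spacing
  tl <- bed_timeline(fractionation_scheme(2.2, 25, label = "SIB 55/25"))
  bed_levels <- c(0, tl$achieved[seq_len(nt - 1)])
  ids <- sprintf("P%03d", seq_len(n))
  w <- config$irregularity$weights
  gamma <- config$irregularity$gamma
  dec <- config$responder_decay

  series <- vector("list", n)
  geometry <- vector("list", n)
  u_lat <- numeric(n)
  flags <- character(0)
  center_mm <- (shape - 1) * spacing / 2

  for (i in seq_len(n)) {
    set.seed(child_seed(seed, i, 1L))
    r0 <- runif(1, config$radius_range[1], config$radius_range[2])
    u1 <- runif(1, 0.75, 1.3)
    u2 <- runif(1, 0.75, 1.3)
    axes0 <- c(r0 * u1, r0 * u2, r0^3 / (r0 * u1 * r0 * u2))
    center <- center_mm + runif(3, -3, 3)
    # large static lobes: shape character, rigidly scaled with the tumour
    nb <- sample(2:4, 1)
    bd <- matrix(rnorm(3 * nb), nb, 3)
    bd <- bd / sqrt(rowSums(bd^2))
    amp0 <- runif(nb, 0.10, 0.30) * r0
    sig <- runif(nb, 0.5, 0.9)
    invw2 <- 1 / (2 * sig^2)
    # zero-mean angular ripple: surface corrugation at ~constant volume;
    # its amplitude carries the boundary-irregularity latent
    nr <- 3L
    rd <- matrix(rnorm(3 * nr), nr, 3)
    rd <- rd / sqrt(rowSums(rd^2))
    ramp0 <- runif(nr, 0.04, 0.08)
    romega <- runif(nr, 5, 8)
    rphase <- runif(nr, 0, 2 * pi)
    mu_d <- runif(1, dec$mean_range[1], dec$mean_range[2])
    f <- clamp(rnorm(nt - 1, mu_d, dec$sd), 0, dec$max)
    u_lat[i] <- rnorm(1)

    g <- c(1, cumprod(1 - f))       # volume ratios
    s <- g^(1 / 3)                  # linear scale factors
    m <- clamp(1 + gamma * u_lat[i] * w, 0.05, 3)

    masks <- vector("list", nt)
    geo <- matrix(NA_real_, nt, 3)
    for (t in tp_keep) {
      msk <- rasterize_timepoint(shape, spacing, center, axes0 * s[t],
                                 bd, amp0 * s[t], invw2,
                                 rd, ramp0 * m[t], romega, rphase)
      if (!any(msk)) { # degenerate shrinkage: clamp to a 1-voxel ROI
        ctr_idx <- clamp(round(center / spacing) + 1L, 1L, shape)
        msk[ctr_idx[1], ctr_idx[2], ctr_idx[3]] <- TRUE
        flags <- c(flags, sprintf("%s: empty mask clamped at t%d", ids[i], t))
      }
      masks[[t]] <- msk
      vol <- sum(msk) * prod(spacing)
      surf <- mesh_surface_area(msk, spacing)
      geo[t, ] <- c(vol, surf, surf / vol)
    }
    if (mode == "labels") {
      series[i] <- list(NULL)
    } else {
      volumes <- NULL
      if (images) {
        set.seed(child_seed(seed, i, 2L))
        volumes <- lapply(seq_len(nt), function(t)
          texture_volume(shape, spacing, masks[[t]], config$noise_sd))
      }
      series[[i]] <- patient_series(ids[i], volumes, masks, bed_levels,
                                    spacing)
    }
    geometry[[i]] <- data.frame(patient_id = ids[i],
                                timepoint = seq_len(nt),
                                bed_gy = bed_levels,
                                volume_mm3 = geo[, 1], surface_mm2 = geo[, 2],
                                av = geo[, 3], stringsAsFactors = FALSE)
  }
  geometry <- do.call(rbind, geometry)

  # embedded predictor: measured delta-AV at the 4th post-simulation level
  # (or the last available level for short series)
  av_mat <- matrix(geometry$av, nrow = nt)
  delta_av <- av_mat[k_sig + 1L, ] / av_mat[1L, ]
  z <- as.numeric(scale(delta_av))
  if (any(!is.finite(z))) z[!is.finite(z)] <- 0

  set.seed(child_seed(seed, 0L, 3L))
  site_uw <- runif(n) < 0.125
  clinical <- data.frame(
    patient_id = ids,
    sex = ifelse(runif(n) < 0.688, "M", "F"),
    age = round(clamp(rnorm(n, 62, 10), 30, 90)),
    cT = sample(c(2L, 3L, 4L), n, replace = TRUE, prob = c(7, 28, 13) / 48),
    cN = as.integer(runif(n) < 35 / 48),
    rt_dose = ifelse(site_uw, 50.4, 55),
    surgery = sample(c("APR", "AR", "TEM_LE", "none"), n, replace = TRUE,
                     prob = c(4, 32, 2, 10) / 48),
    chemo_type = sample(c("with_oxa", "without_oxa", "none"), n,
                        replace = TRUE, prob = c(17, 2, 29) / 48),
    hemoglobin = round(rnorm(n, 13.5, 1.5), 1),
    wbc = round(clamp(rnorm(n, 7, 1.8), 2, 20), 1),
    neutrophils = round(clamp(rnorm(n, 4.5, 1.3), 0.5, 15), 1),
    platelets = round(clamp(rnorm(n, 250, 60), 80, 600)),
    response = as.integer(runif(n) < 1 / 3),
    stringsAsFactors = FALSE)
  lymph <- clamp(rnorm(n, 1.8, 0.5), 0.3, 5)
  clinical$nlr <- round(clinical$neutrophils / lymph, 2)
  clinical$chemo_with_oxa <- as.integer(clinical$chemo_type == "with_oxa")

  eta <- config$effect_size * z + config$chemo_effect * clinical$chemo_with_oxa
  b0 <- uniroot(function(b) mean(plogis(b + eta)) - config$event_prevalence,
                c(-30, 30))$root
  p_event <- plogis(b0 + eta)
  event <- as.integer(runif(n) < p_event)
  clinical$dfs2y <- 1L - event

  structure(list(series = series, clinical = clinical, geometry = geometry,
                 latent = data.frame(patient_id = ids, u = u_lat,
                                     delta_av = delta_av, z = z,
                                     p_event = p_event,
                                     stringsAsFactors = FALSE),
                 flags = flags, signal_timepoint = k_sig,
                 bed_levels = bed_levels, config = config, seed = seed),
            class = "mrgrt_cohort")
}

#' @export
print.mrgrt_cohort <- function(x, ...) {
  tag <- if (is.null(x$series[[1]])) " [labels only]"
         else if (is.null(x$series[[1]]$volumes)) " [masks only]" else ""
  cat(sprintf("mrgrt_cohort: %d patients x %d timepoints, %d events (%.1f%%)%s\n",
              length(x$series), x$config$n_timepoints,
              sum(x$clinical$dfs2y == 0),
              100 * mean(x$clinical$dfs2y == 0), tag))
  invisible(x)
}

#' Cohort characteristics summary
#'
#' Counts and percentages (one decimal) per categorical level, and median
#' plus range for continuous variables — the usual "patient
#' characteristics" table layout.
#'
#' @param records Clinical data frame (as in `cohort$clinical`).
#' @return Data frame of class `cohort_summary` with columns `variable`,
#'   `level`, `n`, `pct`, `median`, `range_lo`, `range_hi`.
#' @export
summarize_cohort <- function(records) {
  if (!nrow(records)) stop("empty cohort")
  N <- nrow(records)
  rows <- list()
  cat_vars <- list(sex = "sex", cT = "cT", cN = "cN", surgery = "surgery",
                   `CT type` = "chemo_type")
  if ("response" %in% names(records))
    cat_vars$`pCR/cCR` <- "response"
  if ("dfs2y" %in% names(records))
    cat_vars$`2yDFS` <- "dfs2y"
  for (nm in names(cat_vars)) {
    col <- cat_vars[[nm]]
    if (!col %in% names(records)) next
    v <- records[[col]]
    if (col %in% c("response", "dfs2y"))
      v <- ifelse(v == 1, "yes", "no")
    tb <- table(v)
    for (lv in names(tb)) {
      rows[[length(rows) + 1L]] <- data.frame(
        variable = nm, level = lv, n = as.integer(tb[[lv]]),
        pct = round(100 * tb[[lv]] / N, 1), median = NA_real_,
        range_lo = NA_real_, range_hi = NA_real_, stringsAsFactors = FALSE)
    }
  }
  for (col in intersect(c("age", "rt_dose", "hemoglobin", "wbc",
                          "neutrophils", "platelets", "nlr"),
                        names(records))) {
    v <- records[[col]]
    rows[[length(rows) + 1L]] <- data.frame(
      variable = col, level = "", n = NA_integer_, pct = NA_real_,
      median = median(v), range_lo = min(v), range_hi = max(v),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("cohort_summary", "data.frame")
  out
}

#' Numeric clinical design matrix for screening
#'
#' Dummy-codes the categorical covariates of a clinical table (as produced
#' by [simulate_cohort()]) so every column is numeric and screenable;
#' keeps `patient_id` and the outcome `dfs2y`.
#'
#' @param clinical Clinical data frame (`cohort$clinical`).
#' @return Data frame of numeric covariates plus `patient_id` and `dfs2y`.
#' @export
clinical_design <- function(clinical) {
  out <- data.frame(patient_id = clinical$patient_id,
                    stringsAsFactors = FALSE)
  out$sex_male <- as.integer(clinical$sex == "M")
  out$age <- clinical$age
  out$cT <- clinical$cT
  out$cN <- clinical$cN
  out$rt_dose <- clinical$rt_dose
  for (lv in c("APR", "AR", "TEM_LE"))
    out[[paste0("surgery_", lv)]] <- as.integer(clinical$surgery == lv)
  out$chemo_with_oxa <- as.integer(clinical$chemo_type == "with_oxa")
  out$chemo_without_oxa <- as.integer(clinical$chemo_type == "without_oxa")
  for (col in c("hemoglobin", "wbc", "neutrophils", "platelets", "nlr",
                "response"))
    out[[col]] <- clinical[[col]]
  out$dfs2y <- clinical$dfs2y
  out
}
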