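#' Simulation configuration for a synthetic CVR cohort
#'
#' Bundles and validates all parameters of the synthetic-cohort generator.
#' Defaults emulate the study conditions the analysis is designed for: a
#' cohort of 17 patients with a completed hypercapnic BOLD-CVR exam, a 6%
#' CO2 block challenge raising end-tidal CO2 by about 10 mmHg over a 40 mmHg
#' baseline, NAWM CVR magnitude 0.054 +/- 0.047 %/mmHg with a deficit to
#' 0.013 inside lesions, dispersion 46 +/- 13 s rising to 59 s in lesions,
#' about 4% of NAWM converting to WMH and about 1.3% of WMH reverting over
#' the two-year interval, and a mean NAWM MD change of 0.13e-4 mm^2/s. The
#' simulated brain is a miniature phantom (default 28 x 28 x 20 voxels of
#' 1 mm); spatial parameters of the CVR/dispersion fields are free knobs
#' with no published counterpart.
#'
#' @param n_subjects Number of subjects. Default 17.
#' @param grid_shape Voxel grid, 3 counts. Default `c(28, 28, 20)`.
#' @param voxel_size_mm Voxel size, mm (length 1 or 3). Default 1 mm.
#' @param tr_s Repetition time, s. Default 3.
#' @param n_volumes BOLD volumes. Default 120 (6 min acquisition).
#' @param etco2_baseline_mmHg Baseline etCO2. Default 40.
#' @param etco2_step_mmHg Hypercapnic step. Default 10.
#' @param etco2_step_sd_mmHg Between-subject SD of the step. Default 1.
#' @param etco2_jitter_sd_mmHg Sample-to-sample jitter SD. Default 0.5.
#' @param block_design List of `c(onset_s, duration_s)` hypercapnic blocks;
#'   must fit within `n_volumes * tr_s`.
#' @param bold_baseline_signal Baseline BOLD signal, a.u. Default 1000.
#' @param bold_noise_sd Temporal noise SD as a fraction of baseline.
#'   Default 0.005 (0.5%).
#' @param cvr_field_params List `mean`, `sd` (%/mmHg) and `smooth_fwhm_mm`
#'   of the spatially correlated true CVR field.
#' @param tau_field_params Same for the true dispersion field (s).
#' @param wmh_cvr_deficit Mean CVR reduction inside lesions, %/mmHg.
#' @param wmh_tau_excess Mean dispersion excess inside lesions, s.
#' @param fate_logit_coefs `c(intercept, per_pct, per_s)` of the logistic
#'   model for NAWM-to-WMH conversion.
#' @param reversion_logit_coefs Same for WMH-to-NAWM reversion (intercept
#'   `-Inf` disables reversion).
#' @param dmd_coefs `c(intercept, per_pct, per_s)` of the linear model for
#'   the MD change (mm^2/s); the slopes apply as such in stable tissue.
#' @param dmd_converting_multiplier Multiplier on both MD-change slopes in
#'   voxels that convert to WMH, reproducing the several-fold stronger
#'   vascular-microstructural coupling observed where lesions form.
#'   Default 5.
#' @param subject_intercept_sd `c(logit = , md = )`: SD of the per-subject
#'   random intercept on the logit scale (both fate models) and on the MD
#'   change scale (mm^2/s).
#' @param md_noise_sd Voxel-level MD-change noise SD, mm^2/s.
#' @param md_baseline_mean,md_baseline_sd Baseline MD field mean and
#'   (smooth) SD, mm^2/s.
#' @param seed Master seed; per-subject seeds are derived as
#'   `seed + 1000 * subject_index`.
#' @return Validated list of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 17,
                       grid_shape = c(28, 28, 20),
                       voxel_size_mm = c(1, 1, 1),
                       tr_s = 3,
                       n_volumes = 120,
                       etco2_baseline_mmHg = 40,
                       etco2_step_mmHg = 10,
                       etco2_step_sd_mmHg = 1,
                       etco2_jitter_sd_mmHg = 0.5,
                       block_design = list(c(90, 60), c(240, 60)),
                       bold_baseline_signal = 1000,
                       bold_noise_sd = 0.005,
                       cvr_field_params = list(mean = 0.054, sd = 0.047,
                                               smooth_fwhm_mm = 4),
                       tau_field_params = list(mean = 46, sd = 13,
                                               smooth_fwhm_mm = 4),
                       wmh_cvr_deficit = 0.041,
                       wmh_tau_excess = 13,
                       fate_logit_coefs = c(intercept = -3.43,
                                            per_pct = log(0.81),
                                            per_s = log(1.06) / 10),
                       reversion_logit_coefs = c(intercept = -4.03,
                                                 per_pct = log(1.06),
                                                 per_s = log(0.95) / 10),
                       dmd_coefs = c(intercept = 1.09e-5,
                                     per_pct = -1.17e-6,
                                     per_s = 4.7e-8),
                       dmd_converting_multiplier = 5,
                       subject_intercept_sd = c(logit = 0.3, md = 1e-6),
                       md_noise_sd = 1.5e-6,
                       md_baseline_mean = 6.28e-4,
                       md_baseline_sd = 2e-5,
                       seed = 1L) {
  voxel_size_mm <- rep_len(voxel_size_mm, 3L)
  stopifnot(n_subjects >= 1, length(grid_shape) == 3, all(grid_shape >= 1),
            all(voxel_size_mm > 0), tr_s > 0, n_volumes >= 1,
            etco2_baseline_mmHg > 0, etco2_step_mmHg >= 0,
            etco2_jitter_sd_mmHg >= 0, etco2_step_sd_mmHg >= 0,
            bold_baseline_signal > 0, bold_noise_sd >= 0,
            md_noise_sd >= 0, md_baseline_sd >= 0,
            all(subject_intercept_sd >= 0),
            length(fate_logit_coefs) == 3,
            length(reversion_logit_coefs) == 3, length(dmd_coefs) == 3)
  total_s <- n_volumes * tr_s
  for (b in block_design) {
    if (length(b) != 2 || b[1] < 0 || b[2] <= 0 || b[1] + b[2] > total_s)
      stop("block (onset ", b[1], " s, duration ", b[2],
           " s) does not fit in the ", total_s, " s acquisition")
  }
  cfg <- as.list(environment())
  cfg$total_s <- NULL
  cfg$b <- NULL
  structure(cfg, class = "sim_config")
}

.subject_seed <- function(config, subject_index) {
  as.integer((config$seed + 1000 * subject_index) %% .Machine$integer.max)
}

#' Generate a block-design etCO2 trace
#'
#' Baseline level plus a step inside each hypercapnic block, with optional
#' Gaussian sample jitter, sampled at the volume mid-times.
#'
#' @param config A [sim_config()].
#' @param seed Seed (default: the config master seed).
#' @param step_mmHg Step height override (default from config).
#' @return An [etco2_trace()].
#' @export
generate_etco2 <- function(config, seed = config$seed,
                           step_mmHg = config$etco2_step_mmHg) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  t <- (seq_len(config$n_volumes) - 0.5) * config$tr_s
  v <- rep(config$etco2_baseline_mmHg, length(t))
  for (b in config$block_design)
    v[t >= b[1] & t < b[1] + b[2]] <- config$etco2_baseline_mmHg + step_mmHg
  if (config$etco2_jitter_sd_mmHg > 0)
    v <- v + rnorm(length(v), 0, config$etco2_jitter_sd_mmHg)
  etco2_trace(t, v)
}

#' Forward-model a BOLD series from true CVR and dispersion maps
#'
#' Per voxel, the etCO2 trace is centred on its median (the resting
#' baseline), convolved with the voxel's exponential dispersion kernel,
#' mean-centred over the acquisition, and scaled by the voxel's CVR
#' magnitude:
#' `S(t) = S0 * (1 + CVR/100 * c(t)) + S0 * noise`. Mean-centring the
#' stimulus ties the CVR magnitude to the voxel's temporal mean signal, the
#' same baseline convention the fitting side uses, so the generative
#' parameters are the estimands of [fit_volume()] exactly.
#'
#' @param true_cvr_map 3D CVR magnitude map, %/mmHg.
#' @param true_tau_map 3D dispersion map, s, all `>= 0`.
#' @param etco2 An [etco2_trace()] sampled at the volume mid-times.
#' @param config A [sim_config()].
#' @param seed Seed for the noise (`NULL` continues the current RNG
#'   stream).
#' @return List of class `bold_series`: `data` (4D array) and `tr_s`.
#' @export
generate_bold <- function(true_cvr_map, true_tau_map, etco2, config,
                          seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  sp <- config$grid_shape
  if (!all(dim(true_cvr_map) == sp) || !all(dim(true_tau_map) == sp))
    stop("maps do not match the configured grid")
  if (any(true_tau_map < 0)) stop("negative dispersion in true_tau_map")
  v <- .trace_values(etco2)
  if (length(v) != config$n_volumes)
    stop("etCO2 trace length does not match n_volumes")
  if (!is.null(seed)) set.seed(seed)
  n_t <- config$n_volumes
  x <- v - median(v)
  s0 <- config$bold_baseline_signal
  nvox <- prod(sp)
  dat <- matrix(0, nvox, n_t)
  cvr <- as.vector(true_cvr_map)
  tau <- as.vector(true_tau_map)
  for (i in seq_len(nvox)) {
    cx <- .conv_causal(x, exp_kernel(tau[i], config$tr_s, n_t))
    dat[i, ] <- s0 * (1 + cvr[i] / 100 * (cx - mean(cx)))
  }
  if (config$bold_noise_sd > 0)
    dat <- dat + s0 * rnorm(length(dat), 0, config$bold_noise_sd)
  structure(list(data = array(dat, c(sp, n_t)), tr_s = config$tr_s),
            class = "bold_series")
}

# --- geometry and field helpers ------------------------------------------

# Normalised ellipsoidal radius: 1 on the ellipsoid with semi-axes
# f * grid/2 around the grid centre.
.ellipsoid_r <- function(grid_shape) {
  cx <- (grid_shape + 1) / 2
  ax <- expand.grid(x = seq_len(grid_shape[1]), y = seq_len(grid_shape[2]),
                    z = seq_len(grid_shape[3]))
  r <- sqrt(((ax$x - cx[1]) / (grid_shape[1] / 2))^2 +
              ((ax$y - cx[2]) / (grid_shape[2] / 2))^2 +
              ((ax$z - cx[3]) / (grid_shape[3] / 2))^2)
  array(r, grid_shape)
}

# Separable Gaussian smoothing with reflection padding.
.conv1_reflect <- function(x, k) {
  m <- (length(k) - 1L) / 2L
  n <- length(x)
  left <- if (m > 0) x[pmin(pmax(m:1, 1), n)] else numeric(0)
  right <- if (m > 0) x[pmin(pmax(n:(n - m + 1L), 1), n)] else numeric(0)
  xp <- c(left, x, right)
  convolve(xp, rev(k), type = "open")[(2 * m + 1):(2 * m + n)]
}

.gauss_smooth <- function(a, fwhm_mm, voxel_size_mm) {
  if (fwhm_mm <= 0) return(a)
  for (d in 1:3) {
    sd_vox <- fwhm_mm / 2.355 / voxel_size_mm[d]
    m <- max(1L, ceiling(3 * sd_vox))
    k <- dnorm(-m:m, sd = sd_vox)
    k <- k / sum(k)
    a <- switch(d,
                apply(a, c(2, 3), .conv1_reflect, k = k),
                aperm(apply(a, c(1, 3), .conv1_reflect, k = k), c(2, 1, 3)),
                aperm(apply(a, c(1, 2), .conv1_reflect, k = k), c(2, 3, 1)))
  }
  a
}

# Smooth standard-normal random field on the grid.
.smooth_field <- function(grid_shape, fwhm_mm, voxel_size_mm) {
  a <- array(rnorm(prod(grid_shape)), grid_shape)
  a <- .gauss_smooth(a, fwhm_mm, voxel_size_mm)
  (a - mean(a)) / sd(a)
}

# Shared generative outcome models: conversion, reversion, MD change.
.draw_outcomes <- function(cvr, tau, is_wmh, config, b_fate, b_rev, b_md) {
  fc <- config$fate_logit_coefs
  rc <- config$reversion_logit_coefs
  dc <- config$dmd_coefs
  n <- length(cvr)
  fate <- character(n)
  nawm <- !is_wmh
  p_conv <- plogis(fc[1] + fc[2] * cvr[nawm] + fc[3] * tau[nawm] + b_fate)
  conv <- runif(sum(nawm)) < p_conv
  fate[nawm] <- ifelse(conv, "NAWM_TO_WMH", "STABLE_NAWM")
  p_rev <- plogis(rc[1] + rc[2] * cvr[is_wmh] + rc[3] * tau[is_wmh] + b_rev)
  rev <- runif(sum(is_wmh)) < p_rev
  fate[is_wmh] <- ifelse(rev, "WMH_TO_NAWM", "STABLE_WMH")
  cm <- if (is.null(config$dmd_converting_multiplier)) 1 else
    config$dmd_converting_multiplier
  mult <- ifelse(fate == "NAWM_TO_WMH", cm, 1)
  dmd <- dc[1] + mult * (dc[2] * cvr + dc[3] * tau) + b_md +
    rnorm(n, 0, config$md_noise_sd)
  list(fate = factor(fate, levels = .FATE_LEVELS[2:5]), delta_md = dmd)
}

# Baseline MD field given true CVR/dispersion (fixed cross-sectional
# coupling mirroring the baseline voxel-wise association).
.md_baseline_coupling <- c(per_pct = -13.4e-6, per_s = 0.30e-6)

#' Generate one synthetic subject
#'
#' Builds a complete co-registered subject: an ellipsoidal miniature brain
#' with a central ventricle, spatially clustered periventricular WMH,
#' spatially smooth true CVR and dispersion fields with a lesion-centred
#' CVR deficit and dispersion excess, the block etCO2 trace and the
#' forward-modelled 4D BOLD series, baseline and follow-up MD maps, and the
#' follow-up WMH mask drawn voxel-wise from the logistic conversion and
#' reversion models with a per-subject random intercept.
#'
#' @param config A [sim_config()].
#' @param subject_index Subject number (1-based); sets the derived seed.
#' @param seed Override for the derived per-subject seed.
#' @return List of class `subject_bundle` with elements `subject_id`,
#'   `etco2`, `bold`, `true_cvr_map`, `true_tau_map`, `wm_mask`,
#'   `ventricle_mask`, `wmh_baseline`, `wmh_followup`, `md_baseline`,
#'   `md_followup`, `icv_ml`, `age_years`, `voxel_size_mm`, `seed`.
#' @export
generate_subject <- function(config, subject_index, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(seed)) seed <- .subject_seed(config, subject_index)
  set.seed(seed)
  sp <- config$grid_shape
  vox <- config$voxel_size_mm

  r <- .ellipsoid_r(sp)
  brain <- r <= 0.95
  ventricle_mask <- r <= 0.12
  wm_mask <- r <= 0.85 & r > 0.35
  icv_ml <- sum(brain) * prod(vox) / 1000

  # Periventricular lesion seeds: sample WM voxels biased towards the
  # ventricles, grow a ball around each.
  wm_idx <- which(wm_mask)
  w <- exp(-4 * r[wm_idx])
  n_seeds <- 5L
  seeds <- sample(wm_idx, n_seeds, prob = w)
  wmh_baseline <- array(FALSE, sp)
  coords <- arrayInd(seeds, sp)
  ax <- arrayInd(seq_len(prod(sp)), sp)
  for (s in seq_len(n_seeds)) {
    rad <- runif(1, 2, 4.2)
    d2 <- ((ax[, 1] - coords[s, 1]) * vox[1])^2 +
      ((ax[, 2] - coords[s, 2]) * vox[2])^2 +
      ((ax[, 3] - coords[s, 3]) * vox[3])^2
    wmh_baseline <- wmh_baseline | array(d2 <= rad^2, sp)
  }
  wmh_baseline <- wmh_baseline & wm_mask

  # True fields: smooth Gaussian field plus a lesion-centred deficit whose
  # weight is the smoothed lesion mask, scaled so the lesion mean matches
  # the configured NAWM-WMH contrast.
  cvrp <- config$cvr_field_params
  taup <- config$tau_field_params
  cvr <- cvrp$mean + cvrp$sd * .smooth_field(sp, cvrp$smooth_fwhm_mm, vox)
  tau <- taup$mean + taup$sd * .smooth_field(sp, taup$smooth_fwhm_mm, vox)
  wsm <- .gauss_smooth(array(as.numeric(wmh_baseline), sp), 3, vox)
  if (any(wmh_baseline) && mean(wsm[wmh_baseline]) > 0) {
    wsm <- wsm / mean(wsm[wmh_baseline])
    cvr <- cvr - config$wmh_cvr_deficit * wsm
    tau <- tau + config$wmh_tau_excess * wsm
  }
  tau <- pmin(pmax(tau, 1.5), 115)

  # etCO2 and BOLD (noise drawn from the subject's RNG stream).
  step <- rnorm(1, config$etco2_step_mmHg, config$etco2_step_sd_mmHg)
  etco2 <- generate_etco2(config, seed = NULL, step_mmHg = step)
  bold <- generate_bold(cvr, tau, etco2, config, seed = NULL)

  # Baseline MD: level + cross-sectional coupling to the true fields +
  # smooth anatomical variation + lesion elevation.
  md_baseline <- config$md_baseline_mean +
    .md_baseline_coupling["per_pct"] * (cvr - cvrp$mean) +
    .md_baseline_coupling["per_s"] * (tau - taup$mean) +
    config$md_baseline_sd * .smooth_field(sp, 6, vox) +
    1.5e-4 * wsm
  md_baseline <- pmax(md_baseline, 1e-4)

  # Longitudinal outcomes.
  b_fate <- rnorm(1, 0, config$subject_intercept_sd["logit"])
  b_rev <- rnorm(1, 0, config$subject_intercept_sd["logit"])
  b_md <- rnorm(1, 0, config$subject_intercept_sd["md"])
  wm_lin <- which(wm_mask)
  oc <- .draw_outcomes(cvr[wm_lin], tau[wm_lin], wmh_baseline[wm_lin],
                       config, b_fate, b_rev, b_md)
  wmh_followup <- array(FALSE, sp)
  wmh_followup[wm_lin] <- oc$fate %in% c("NAWM_TO_WMH", "STABLE_WMH")
  md_followup <- md_baseline
  md_followup[wm_lin] <- md_baseline[wm_lin] + oc$delta_md

  structure(list(
    subject_id = sprintf("sub-%02d", subject_index),
    etco2 = etco2, bold = bold,
    true_cvr_map = cvr, true_tau_map = tau,
    wm_mask = wm_mask, ventricle_mask = ventricle_mask,
    wmh_baseline = wmh_baseline, wmh_followup = wmh_followup,
    md_baseline = md_baseline, md_followup = md_followup,
    icv_ml = icv_ml,
    age_years = round(min(max(rnorm(1, 51, 10), 28), 67)),
    voxel_size_mm = vox, tr_s = config$tr_s, seed = seed
  ), class = "subject_bundle")
}

#' Generate a synthetic cohort
#'
#' Generates `n_subjects` subject bundles with deterministically derived
#' per-subject seeds and, optionally, writes them to disk as NIfTI volumes
#' plus CSV traces with a cohort manifest (see [write_cohort()]).
#'
#' @param config A [sim_config()].
#' @param out_dir Optional output directory; created if missing.
#' @return List of class `cohort`: `subjects` (list of bundles), `config`,
#'   `manifest` (data frame: subject id, seed, age, ICV, etCO2 challenge
#'   amplitude, true field means).
#' @export
generate_cohort <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  subjects <- lapply(seq_len(config$n_subjects),
                     function(i) generate_subject(config, i))
  manifest <- do.call(rbind, lapply(subjects, function(s) {
    data.frame(subject_id = s$subject_id, seed = s$seed,
               age_years = s$age_years, icv_ml = s$icv_ml,
               delta_etco2_mmHg = delta_etco2(s$etco2),
               true_cvr_mean = mean(s$true_cvr_map[s$wm_mask]),
               true_tau_mean = mean(s$true_tau_map[s$wm_mask]))
  }))
  cohort <- structure(list(subjects = subjects, config = config,
                           manifest = manifest), class = "cohort")
  if (!is.null(out_dir)) write_cohort(cohort, out_dir)
  cohort
}

#' Simulate a concatenated voxel table directly from the generative model
#'
#' Fast path for statistical validation: draws per-voxel true CVR magnitude
#' and dispersion from the configured field marginals (with the lesion
#' contrast applied to WMH voxels), then draws tissue fate and MD change
#' from the same logistic and linear models used by [generate_subject()],
#' skipping image formation. The returned table has the same columns as
#' [build_voxel_table()], with the generative truth attached as attribute
#' `truth`.
#'
#' @param config A [sim_config()].
#' @param n_voxels_per_subject White matter voxels per subject. Default
#'   2000.
#' @param wmh_fraction Fraction of voxels that are WMH at baseline.
#'   Default 0.18.
#' @param seed Seed (default: config master seed).
#' @return Data frame: `subject_id`, `voxel_index`, `cvr_mag`, `tau_s`,
#'   `delta_etco2`, `fate`, `md_baseline`, `delta_md`, `age_years`.
#' @export
simulate_voxel_table <- function(config, n_voxels_per_subject = 2000,
                                 wmh_fraction = 0.18, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  cvrp <- config$cvr_field_params
  taup <- config$tau_field_params
  rows <- lapply(seq_len(config$n_subjects), function(i) {
    n <- n_voxels_per_subject
    is_wmh <- runif(n) < wmh_fraction
    cvr <- rnorm(n, cvrp$mean, cvrp$sd) -
      config$wmh_cvr_deficit * is_wmh
    tau <- pmin(pmax(rnorm(n, taup$mean, taup$sd) +
                       config$wmh_tau_excess * is_wmh, 1.5), 115)
    b_fate <- rnorm(1, 0, config$subject_intercept_sd["logit"])
    b_rev <- rnorm(1, 0, config$subject_intercept_sd["logit"])
    b_md <- rnorm(1, 0, config$subject_intercept_sd["md"])
    oc <- .draw_outcomes(cvr, tau, is_wmh, config, b_fate, b_rev, b_md)
    md0 <- config$md_baseline_mean +
      .md_baseline_coupling["per_pct"] * (cvr - cvrp$mean) +
      .md_baseline_coupling["per_s"] * (tau - taup$mean) +
      rnorm(n, 0, config$md_baseline_sd)
    data.frame(
      subject_id = sprintf("sub-%02d", i),
      voxel_index = seq_len(n),
      cvr_mag = cvr, tau_s = tau,
      delta_etco2 = rnorm(1, config$etco2_step_mmHg,
                          config$etco2_step_sd_mmHg),
      fate = oc$fate, md_baseline = md0, delta_md = oc$delta_md,
      age_years = round(min(max(rnorm(1, 51, 10), 28), 67))
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$subject_id <- factor(out$subject_id)
  attr(out, "truth") <- list(
    fate_logit_coefs = config$fate_logit_coefs,
    reversion_logit_coefs = config$reversion_logit_coefs,
    dmd_coefs = config$dmd_coefs,
    dmd_converting_multiplier = config$dmd_converting_multiplier)
  out
}
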