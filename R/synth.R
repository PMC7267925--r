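# Synthetic resting-state cohort generator.
#
# Emulates a small placebo-arm cohort already aligned on a common grid: an
# ellipsoidal brain with interior WM/CSF compartments, a planted seed region
# sharing a band-limited latent signal, target regions coupled to the seed
# with subject-varying strength beta_s, compartment nuisance signals leaking
# into gray matter, slow drifts, motion random walks with injected spike
# frames, and an outcome (HDRS percent change) linearly driven by beta_s.
# Ground truth (beta_s, spike frames, noiseless outcome) is returned so every
# downstream stage can be checked against what was planted.

#' Synthetic cohort configuration
#'
#' Defaults describe the desk-scale world: a 20 x 20 x 14 grid of 3-mm
#' voxels, 150 timepoints at TR = 2 s and 22 subjects whose outcome
#' distribution mimics the published cohort (percent-change mean ~9.3%, SD
#' ~26%; 16/22 female; age ~ N(43, 12.24) truncated to 18-61). Coupling
#' beta_s ~ N(0.8, 0.25) with outcome slope 0.7, intercept -0.467 and
#' residual SD 0.19. The full acquisition-length run (300 timepoints) is available
#' via `n_timepoints`.
#'
#' @param grid_shape Integer 3-vector of voxels per axis (each >= 4).
#' @param voxel_size_mm Isotropic voxel size in mm.
#' @param n_timepoints Number of volumes (>= 20).
#' @param tr_seconds Repetition time in seconds.
#' @param n_subjects Number of subjects (>= 4).
#' @param seed_center_mm World coordinate of the planted seed ("rACC") region.
#' @param target_centers_mm List of world coordinates of planted target
#'   regions (precuneus/PCC- and MFG-like analogs).
#' @param region_radius_mm Radius of planted regions in mm.
#' @param coupling_mean,coupling_sd Across-subject distribution of the
#'   seed-to-target coupling beta_s.
#' @param outcome_slope Effect of beta_s on the fractional outcome.
#' @param outcome_intercept Outcome intercept (fraction).
#' @param outcome_noise_sd Residual SD of the outcome (fraction).
#' @param covariate_effects Length-3 slopes of centered age, sex and mean FD
#'   on the outcome.
#' @param spike_rate Per-frame probability of an artifact spike, in [0, 0.2].
#' @param spike_amplitude_sd_units Spike amplitude in units of the voxel
#'   noise SD.
#' @param drift_amplitude Amplitude of slow per-voxel drift (signal units).
#' @param rng_seed Integer seed; the entire cohort is reproducible from it.
#' @return A `synth_config` list.
#' @export
synth_config <- function(grid_shape = c(20L, 20L, 14L),
                         voxel_size_mm = 3,
                         n_timepoints = 150L,
                         tr_seconds = 2,
                         n_subjects = 22L,
                         seed_center_mm = NULL,
                         target_centers_mm = NULL,
                         region_radius_mm = 6,
                         coupling_mean = 0.8,
                         coupling_sd = 0.25,
                         outcome_slope = 0.7,
                         outcome_intercept = -0.467,
                         outcome_noise_sd = 0.19,
                         covariate_effects = c(0, 0, 0),
                         spike_rate = 0.02,
                         spike_amplitude_sd_units = 5,
                         drift_amplitude = 1.5,
                         rng_seed = 20191021L) {
  # region centers default to fixed fractions of the brain half-extent so
  # that the desk-scale grid plants the seed exactly at the rACC anchor
  # (0, 38, 4) and the targets at PCC- and MFG-like analogs
  half <- voxel_size_mm * (as.integer(grid_shape) - 1) / 2
  anchor <- c(0, 30, 5)
  if (is.null(seed_center_mm))
    seed_center_mm <- anchor + c(0, 8 / 28.5, -1 / 19.5) * half
  if (is.null(target_centers_mm))
    target_centers_mm <- list(
      anchor + c(0, 22 / 28.5, 5 / 19.5) * half,
      anchor + c(-15 / 28.5, 14 / 28.5, 9 / 19.5) * half)
  cfg <- list(grid_shape = as.integer(grid_shape),
              voxel_size_mm = voxel_size_mm,
              n_timepoints = as.integer(n_timepoints),
              tr_seconds = tr_seconds,
              n_subjects = as.integer(n_subjects),
              seed_center_mm = as.numeric(seed_center_mm),
              target_centers_mm = lapply(target_centers_mm, as.numeric),
              region_radius_mm = region_radius_mm,
              coupling_mean = coupling_mean, coupling_sd = coupling_sd,
              outcome_slope = outcome_slope,
              outcome_intercept = outcome_intercept,
              outcome_noise_sd = outcome_noise_sd,
              covariate_effects = as.numeric(covariate_effects),
              spike_rate = spike_rate,
              spike_amplitude_sd_units = spike_amplitude_sd_units,
              drift_amplitude = drift_amplitude,
              rng_seed = as.integer(rng_seed))
  class(cfg) <- "synth_config"
  validate_synth_config(cfg)
  cfg
}

#' Validate a synthetic cohort configuration
#'
#' @param cfg A `synth_config`.
#' @param band_low_hz Optional band-pass low cutoff to be applied downstream;
#'   when supplied, runs shorter than `10 / band_low_hz` seconds trigger a
#'   warning (too few slow cycles for stable filtering).
#' @return `cfg`, invisibly; errors on invalid settings.
#' @export
validate_synth_config <- function(cfg, band_low_hz = NULL) {
  with(cfg, {
    if (length(grid_shape) != 3L || any(grid_shape < 4L))
      stop("degenerate grid: every axis needs >= 4 voxels")
    stopifnot(voxel_size_mm > 0, tr_seconds > 0)
    if (n_timepoints < 20L) stop("n_timepoints must be >= 20")
    if (n_subjects < 4L) stop("n_subjects must be >= 4")
    if (coupling_sd < 0) stop("coupling_sd must be >= 0")
    if (outcome_noise_sd < 0) stop("outcome_noise_sd must be >= 0")
    if (spike_rate < 0 || spike_rate > 0.2)
      stop("spike_rate must lie in [0, 0.2]")
    stopifnot(spike_amplitude_sd_units > 0, drift_amplitude >= 0,
              region_radius_mm > 0, length(covariate_effects) == 3L)
  })
  geom <- .synth_geometry(cfg)
  centers <- c(list(cfg$seed_center_mm), cfg$target_centers_mm)
  for (ct in centers) {
    idx <- world_to_voxel(geom$affine, ct, dim = cfg$grid_shape)
    if (!geom$brain[idx[1] + 1, idx[2] + 1, idx[3] + 1])
      stop("region center (", paste(ct, collapse = ", "),
           ") falls outside the brain mask")
  }
  if (!is.null(band_low_hz) &&
      cfg$n_timepoints * cfg$tr_seconds < 10 / band_low_hz)
    warning("run length ", cfg$n_timepoints * cfg$tr_seconds,
            " s is shorter than 10 cycles of the ", band_low_hz,
            " Hz low cutoff")
  invisible(cfg)
}

# Grid geometry: affine placing the grid center at a fixed world anchor, an
# ellipsoidal brain, a CSF blob and a WM shell in the posterior interior.
.synth_geometry <- function(cfg) {
  shp <- cfg$grid_shape
  vox <- cfg$voxel_size_mm
  anchor <- c(0, 30, 5)                       # world coord of the grid center
  affine <- diag(c(vox, vox, vox, 1))
  affine[1:3, 4] <- anchor - vox * (shp - 1) / 2
  ax <- lapply(1:3, function(a) affine[a, a] * (seq_len(shp[a]) - 1) + affine[a, 4])
  half <- vox * (shp - 1) / 2
  X <- array(ax[[1]], dim = shp)
  Y <- array(rep(ax[[2]], each = shp[1]), dim = shp)
  Z <- array(rep(ax[[3]], each = shp[1] * shp[2]), dim = shp)
  brain <- ((X - anchor[1]) / half[1])^2 + ((Y - anchor[2]) / half[2])^2 +
    ((Z - anchor[3]) / half[3])^2 <= 1
  # interior compartments around a posterior focus, scaled with grid extent
  focus <- anchor + c(0, -0.5 * half[2], 0)
  r2 <- (X - focus[1])^2 + (Y - focus[2])^2 + (Z - focus[3])^2
  # compartment radii scale with the grid but never shrink below a floor
  # that guarantees enough voxels for 5 principal components per mask
  csf_r <- max(0.18 * min(half), 1.4 * vox)
  wm_r <- max(0.45 * min(half), 2.4 * vox)
  csf <- brain & r2 <= csf_r^2
  wm <- brain & r2 > csf_r^2 & r2 <= wm_r^2
  gm <- brain & !wm & !csf
  list(affine = affine, brain = brain, gm = gm, wm = wm, csf = csf,
       X = X, Y = Y, Z = Z)
}

# Band-limited latent signal: sum of sinusoids inside [0.015, 0.095] Hz,
# unit variance.
.band_limited_signal <- function(n_t, tr, n_components = 8L) {
  tt <- (seq_len(n_t) - 1) * tr
  f <- stats::runif(n_components, 0.015, 0.095)
  a <- stats::runif(n_components, 0.5, 1)
  ph <- stats::runif(n_components, 0, 2 * pi)
  s <- drop(cos(outer(tt, f * 2 * pi) + rep(ph, each = n_t)) %*% a)
  s / stats::sd(s)
}

# Column-wise band-limited noise: white noise Fourier-filtered to the slow
# band, each column rescaled to unit SD. Gives every voxel intrinsic in-band
# power (as real resting-state data has), preventing the planted latent from
# saturating Fisher-z connectivity after band-pass denoising.
.band_noise <- function(n_t, n_cols, tr) {
  W <- matrix(stats::rnorm(n_t * n_cols), n_t)
  freq <- (seq_len(n_t) - 1) / (n_t * tr)
  freq <- pmin(freq, 1 / tr - freq)
  keep <- freq >= 0.015 & freq <= 0.095
  Wf <- stats::mvfft(W)
  Wf[!keep, ] <- 0
  out <- Re(stats::mvfft(Wf, inverse = TRUE)) / n_t
  sweep(out, 2, apply(out, 2, stats::sd), "/")
}

# Bounded random walk: cumulative normal increments reflected at +/- bound.
.bounded_walk <- function(n_t, step_sd, bound) {
  x <- cumsum(stats::rnorm(n_t, 0, step_sd))
  # reflect into [-bound, bound]
  y <- (x + bound) %% (4 * bound)
  y <- ifelse(y > 2 * bound, 4 * bound - y, y)
  y - bound
}

#' Generate a synthetic cohort
#'
#' @param config A [synth_config()].
#' @return A list of class `synth_cohort` with elements `runs` (list of
#'   [bold_run()]), `masks` ([mask_set()]), `motion` (list of
#'   [motion_trace()]), `subjects` (data.frame with demographics, HDRS scores
#'   and derived percent change), `truth` (per-subject `beta`, `spikes`
#'   (1-based frame indices), `latent` seed signals and
#'   `outcome_noiseless`), and `config`.
#' @export
generate_cohort <- function(config) {
  validate_synth_config(config)
  cfg <- config
  set.seed(cfg$rng_seed)
  geom <- .synth_geometry(cfg)
  masks <- mask_set(geom$brain, geom$gm, geom$wm, geom$csf, geom$affine)
  shp <- cfg$grid_shape
  n_t <- cfg$n_timepoints
  n_s <- cfg$n_subjects
  n_vox <- prod(shp)
  vox_idx <- list(brain = which(geom$brain), gm = which(geom$gm),
                  wm = which(geom$wm), csf = which(geom$csf))

  region_voxels <- function(center) {
    d2 <- (geom$X - center[1])^2 + (geom$Y - center[2])^2 +
      (geom$Z - center[3])^2
    which(geom$brain & d2 <= cfg$region_radius_mm^2)
  }
  seed_vox <- region_voxels(cfg$seed_center_mm)
  target_vox <- unique(unlist(lapply(cfg$target_centers_mm, region_voxels)))
  target_vox <- setdiff(target_vox, seed_vox)

  # subject-level draws (fixed order for determinism)
  beta <- stats::rnorm(n_s, cfg$coupling_mean, cfg$coupling_sd)
  age <- round(pmin(pmax(stats::rnorm(n_s, 43, 12.24), 18), 61))
  sex <- stats::rbinom(n_s, 1, 16 / 22)
  hdrs_base <- pmax(8, round(stats::rnorm(n_s, 22, 6)))
  out_noise <- stats::rnorm(n_s, 0, cfg$outcome_noise_sd)

  noise_sd <- 0.8
  leak <- 0.15
  runs <- vector("list", n_s)
  motion <- vector("list", n_s)
  spikes <- vector("list", n_s)
  latents <- vector("list", n_s)
  mean_fd <- numeric(n_s)

  for (s in seq_len(n_s)) {
    latent <- .band_limited_signal(n_t, cfg$tr_seconds)
    latents[[s]] <- latent
    wm_sig <- .band_limited_signal(n_t, cfg$tr_seconds) +
      0.5 * stats::rnorm(n_t)
    csf_sig <- .band_limited_signal(n_t, cfg$tr_seconds) +
      0.5 * stats::rnorm(n_t)

    dat <- matrix(stats::rnorm(n_t * n_vox, 0, 0.01), n_t, n_vox)
    dat[, vox_idx$brain] <- stats::rnorm(n_t * length(vox_idx$brain), 0,
                                         noise_sd)
    # intrinsic slow fluctuations at every brain voxel (SD 0.6 vs latent 1),
    # spatially smooth like real resting-state signal so that later spatial
    # smoothing does not preferentially suppress them against the latent
    intr <- .band_noise(n_t, n_vox, cfg$tr_seconds)
    intr_run <- bold_run(array(t(intr), dim = c(shp, n_t)), cfg$tr_seconds,
                         geom$affine, "intrinsic")
    intr <- .run_matrix(smooth_gaussian(intr_run, 6))
    intr <- sweep(intr, 2, pmax(apply(intr, 2, stats::sd), 1e-12), "/")
    dat[, vox_idx$brain] <- dat[, vox_idx$brain] +
      0.6 * intr[, vox_idx$brain]
    dat[, vox_idx$gm] <- dat[, vox_idx$gm] +
      leak * (wm_sig + csf_sig)
    dat[, vox_idx$wm] <- dat[, vox_idx$wm] * (0.5 / noise_sd) + wm_sig
    dat[, vox_idx$csf] <- dat[, vox_idx$csf] * (0.5 / noise_sd) + csf_sig
    dat[, seed_vox] <- dat[, seed_vox] + latent
    dat[, target_vox] <- dat[, target_vox] + beta[s] * latent

    # slow drift: per-voxel linear slope and per-voxel half-cosine amplitude
    # (drift varies spatially; a perfectly global drift would alias into a
    # rank-one shared signal that swamps region-mean correlations)
    if (cfg$drift_amplitude > 0) {
      slope <- stats::runif(n_vox, -1, 1) * cfg$drift_amplitude
      tt <- seq_len(n_t) / n_t - 0.5
      dat <- dat + outer(tt, slope)
      camp <- stats::runif(length(vox_idx$brain), -1, 1) *
        0.5 * cfg$drift_amplitude
      dat[, vox_idx$brain] <- dat[, vox_idx$brain] +
        outer(cos(pi * seq_len(n_t) / n_t), camp)
    }

    # motion: bounded random walks; spikes add a persisting step
    mp <- cbind(.bounded_walk(n_t, 0.02, 1), .bounded_walk(n_t, 0.02, 1),
                .bounded_walk(n_t, 0.02, 1),
                .bounded_walk(n_t, 4e-4, 0.02), .bounded_walk(n_t, 4e-4, 0.02),
                .bounded_walk(n_t, 4e-4, 0.02))
    spk <- which(stats::runif(n_t) < cfg$spike_rate)
    spk <- spk[spk > 1L]                     # frame 1 has no FD signal
    for (k in spk) {
      jump <- cfg$spike_amplitude_sd_units * noise_sd *
        abs(stats::rnorm(1, 1, 0.2))
      dat[k, vox_idx$brain] <- dat[k, vox_idx$brain] + jump
      axis_t <- sample.int(3, 1)
      axis_r <- sample.int(3, 1) + 3L
      mp[k:n_t, axis_t] <- mp[k:n_t, axis_t] + stats::rnorm(1, 0, 0.4)
      mp[k:n_t, axis_r] <- mp[k:n_t, axis_r] + stats::rnorm(1, 0, 0.006)
    }
    spikes[[s]] <- spk
    mt <- motion_trace(mp)
    motion[[s]] <- mt
    mean_fd[s] <- mean_framewise_displacement(framewise_displacement(mt))

    dat <- dat + 100                          # raw-intensity baseline
    arr <- array(t(dat), dim = c(shp, n_t))
    runs[[s]] <- bold_run(arr, cfg$tr_seconds, geom$affine,
                          subject_id = sprintf("sub-%02d", s))
  }

  # outcome: intercept + slope * beta + covariate terms + noise, then mapped
  # to integer HDRS pairs so that pct_change(baseline, post) is exact
  cov_term <- cfg$covariate_effects[1] * (age - 43) +
    cfg$covariate_effects[2] * (sex - 16 / 22) +
    cfg$covariate_effects[3] * (mean_fd - mean(mean_fd))
  noiseless <- cfg$outcome_intercept + cfg$outcome_slope * beta + cov_term
  pct_raw <- noiseless + out_noise
  hdrs_post <- pmax(0, round(hdrs_base * (1 - pct_raw)))
  subjects <- data.frame(
    subject_id = sprintf("sub-%02d", seq_len(n_s)),
    age = age, sex = sex,
    hdrs_baseline = hdrs_base, hdrs_post = hdrs_post,
    hdrs_pct_change = pct_change(hdrs_base, hdrs_post),
    mean_fd = mean_fd, stringsAsFactors = FALSE)

  structure(list(runs = runs, masks = masks, motion = motion,
                 subjects = subjects,
                 truth = list(beta = beta, spikes = spikes,
                              latent = latents,
                              outcome_noiseless = noiseless),
                 config = cfg),
            class = "synth_cohort")
}

#' Write a synthetic cohort to disk
#'
#' One NIfTI run and one motion text file per subject, four mask NIfTIs, a
#' subjects TSV and a JSON manifest echoing the configuration.
#'
#' @param cohort A `synth_cohort` from [generate_cohort()].
#' @param directory Output directory; must be empty unless
#'   `overwrite = TRUE`.
#' @param overwrite Allow writing into a non-empty directory.
#' @return The manifest as a list (also written to `manifest.json`),
#'   invisibly.
#' @export
write_cohort <- function(cohort, directory, overwrite = FALSE) {
  stopifnot(inherits(cohort, "synth_cohort"))
  if (dir.exists(directory) && length(dir(directory)) > 0 && !overwrite)
    stop("directory ", directory, " is not empty (use overwrite = TRUE)")
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  cfg <- cohort$config
  runs <- character(0)
  motion <- character(0)
  for (s in seq_along(cohort$runs)) {
    id <- cohort$runs[[s]]$subject_id
    rp <- file.path(directory, paste0(id, "_bold.nii"))
    write_nifti(cohort$runs[[s]]$data, cohort$runs[[s]]$affine, rp,
                datatype = "float64", tr = cfg$tr_seconds,
                descrip = "placeboconn synthetic bold")
    mp <- file.path(directory, paste0(id, "_motion.txt"))
    write_motion(cohort$motion[[s]], mp)
    runs <- c(runs, rp)
    motion <- c(motion, mp)
  }
  mask_paths <- list()
  for (nm in c("brain", "gm", "wm", "csf")) {
    p <- file.path(directory, paste0("mask_", nm, ".nii"))
    write_nifti(array(as.double(cohort$masks[[nm]]),
                      dim = dim(cohort$masks[[nm]])),
                cohort$masks$affine, p, datatype = "uint8")
    mask_paths[[nm]] <- p
  }
  sp <- file.path(directory, "subjects.tsv")
  write_subjects(cohort$subjects, sp)
  manifest <- list(rng_seed = cfg$rng_seed,
                   config = unclass(cfg),
                   runs = runs, motion = motion, masks = mask_paths,
                   subjects = sp)
  jsonlite::write_json(manifest, file.path(directory, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Read a cohort previously written by [write_cohort()]
#'
#' @param directory Directory containing `manifest.json`.
#' @return A `synth_cohort`-shaped list (without ground truth).
#' @export
read_cohort <- function(directory) {
  man <- jsonlite::read_json(file.path(directory, "manifest.json"),
                             simplifyVector = TRUE)
  tr <- man$config$tr_seconds
  runs <- lapply(seq_along(man$runs), function(i)
    read_bold(man$runs[i], tr, subject_id = sprintf("sub-%02d", i)))
  motion <- lapply(man$motion, read_motion)
  rm <- function(p) read_nifti(p)$data > 0.5
  aff <- read_nifti(man$masks$brain)$affine
  masks <- mask_set(rm(man$masks$brain), rm(man$masks$gm), rm(man$masks$wm),
                    rm(man$masks$csf), aff)
  subjects <- read_subjects(man$subjects)
  structure(list(runs = runs, masks = masks, motion = motion,
                 subjects = subjects, truth = NULL, config = man$config),
            class = "synth_cohort")
}
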