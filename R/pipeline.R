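# Config-driven orchestration: validates a JSON pipeline configuration,
# runs denoising -> connectivity -> group inference -> prediction for one or
# both confound strategies, and writes every artifact with provenance
# (config hash, seed, stage parameters).

#' Build a pipeline configuration
#'
#' @param cohort_dir Directory holding a cohort written by [write_cohort()]
#'   (runs, masks, motion, subjects table, manifest).
#' @param output_dir Output directory for all artifacts.
#' @param denoise_strategy `"acompcor"`, `"gsr"`, or `"both"`.
#' @param denoise A [denoise_params()].
#' @param seed A [seed_spec()].
#' @param prediction A [prediction_spec()].
#' @param group_voxel_p,group_cluster_alpha,group_n_perm Group-map
#'   thresholds and permutation count.
#' @param rng_seed Global seed; per-stage seeds are derived from it by
#'   stable hashing of stage names.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(cohort_dir, output_dir,
                            denoise_strategy = c("acompcor", "gsr", "both"),
                            denoise = denoise_params(),
                            seed = seed_spec(),
                            prediction = prediction_spec(),
                            group_voxel_p = 0.001,
                            group_cluster_alpha = 0.05,
                            group_n_perm = 499L,
                            rng_seed = 1L) {
  denoise_strategy <- match.arg(denoise_strategy)
  structure(list(cohort_dir = cohort_dir, output_dir = output_dir,
                 denoise_strategy = denoise_strategy, denoise = denoise,
                 seed = seed, prediction = prediction,
                 group_voxel_p = group_voxel_p,
                 group_cluster_alpha = group_cluster_alpha,
                 group_n_perm = as.integer(group_n_perm),
                 rng_seed = as.integer(rng_seed)),
            class = "pipeline_config")
}

#' Load a pipeline configuration from JSON
#' @param path JSON config path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  dn <- do.call(denoise_params, as.list(j$denoise %||% list()))
  sd <- if (is.null(j$seed)) seed_spec() else
    seed_spec(unlist(j$seed$center_mm), j$seed$diameter_mm %||% 6)
  pr <- do.call(prediction_spec, as.list(j$prediction %||% list()))
  pipeline_config(j$cohort_dir, j$output_dir,
                  j$denoise_strategy %||% "acompcor",
                  denoise = dn, seed = sd, prediction = pr,
                  group_voxel_p = j$group_voxel_p %||% 0.001,
                  group_cluster_alpha = j$group_cluster_alpha %||% 0.05,
                  group_n_perm = j$group_n_perm %||% 499L,
                  rng_seed = j$rng_seed %||% 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# deterministic per-stage seed derived from the global seed and stage name
.stage_seed <- function(rng_seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  (as.numeric(rng_seed) * 7919 + h * 104729) %% 2147483647
}

#' Validate a pipeline configuration
#'
#' Checks paths, shape consistency and Nyquist constraints; returns a
#' data.frame of findings with severities rather than stopping at the first
#' problem.
#'
#' @param config A `pipeline_config`.
#' @return data.frame with columns `severity` (`"error"`/`"warning"`) and
#'   `message`; zero rows means the config is clean.
#' @export
validate_config <- function(config) {
  findings <- data.frame(severity = character(0), message = character(0))
  add <- function(sev, msg)
    rbind(findings, data.frame(severity = sev, message = msg))
  man_path <- file.path(config$cohort_dir, "manifest.json")
  if (!file.exists(man_path))
    return(add("error", paste0("missing cohort manifest: ", man_path)))
  man <- jsonlite::read_json(man_path, simplifyVector = TRUE)
  for (i in seq_along(man$runs)) {
    if (!file.exists(man$runs[i]))
      findings <- add("error", paste0("missing BOLD run for subject ", i,
                                      ": ", man$runs[i]))
    if (!file.exists(man$motion[i]))
      findings <- add("error", paste0("missing motion file for subject ", i,
                                      ": ", man$motion[i]))
  }
  for (nm in names(man$masks))
    if (!file.exists(man$masks[[nm]]))
      findings <- add("error", paste0("missing mask: ", man$masks[[nm]]))
  if (!file.exists(man$subjects))
    findings <- add("error", paste0("missing subjects table: ", man$subjects))
  tr <- man$config$tr_seconds
  nyq <- 1 / (2 * tr)
  if (config$denoise$band_high_hz >= nyq)
    findings <- add("error", sprintf(
      "band_high_hz (%g) is not below Nyquist (%g Hz) at TR = %g s",
      config$denoise$band_high_hz, nyq, tr))
  dur <- man$config$n_timepoints * tr
  if (dur < 10 / config$denoise$band_low_hz)
    findings <- add("warning", sprintf(
      "run length %g s is under 10 cycles of the %g Hz low cutoff",
      dur, config$denoise$band_low_hz))
  findings
}

# denoise one subject and return both connectivity maps
.subject_maps <- function(run, motion, masks, strategy, dn, seed) {
  outl <- detect_outliers(run, motion, brain_mask = masks$brain)
  conf <- assemble_confounds(motion, outl, run, masks, strategy)
  sm <- if (dn$smoothing_fwhm_mm > 0)
    smooth_gaussian(run, dn$smoothing_fwhm_mm) else run
  den <- run_denoise_chain(sm, conf, dn)
  seed_ts <- seed_timeseries(den, seed, masks$brain)
  list(gbc = gbc_map(den, masks$brain),
       seed_fc_z = seed_fc_map(den, seed_ts, masks$brain),
       confounds = conf, outliers = outl)
}

.run_strategy <- function(cohort, config, strategy, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dn <- config$denoise
  n <- length(cohort$runs)
  gbc_maps <- vector("list", n)
  fc_maps <- vector("list", n)
  for (s in seq_len(n)) {
    sm <- .subject_maps(cohort$runs[[s]], cohort$motion[[s]], cohort$masks,
                        strategy, dn, config$seed)
    gbc_maps[[s]] <- sm$gbc
    fc_maps[[s]] <- sm$seed_fc_z
    id <- cohort$runs[[s]]$subject_id
    write_map(sm$gbc, file.path(out_dir, paste0(id, "_gbc.nii")))
    write_map(sm$seed_fc_z, file.path(out_dir, paste0(id, "_seedfc.nii")))
    write_confounds(sm$confounds,
                    file.path(out_dir, paste0(id, "_confounds.tsv")))
  }
  subjects <- cohort$subjects
  design <- group_design(age = subjects$age, sex = subjects$sex,
                         mean_fd = subjects$mean_fd)
  grp <- cluster_fwe(fc_maps, design,
                     voxel_p = config$group_voxel_p,
                     cluster_alpha = config$group_cluster_alpha,
                     n_perm = config$group_n_perm,
                     rng_seed = .stage_seed(config$rng_seed, "group"))
  write_map(grp$t_map, file.path(out_dir, "group_seedfc_t.nii"))
  write_cluster_table(grp$clusters,
                      file.path(out_dir, "group_seedfc_clusters.tsv"))

  predictions <- list()
  for (kind in c("gbc", "seed_fc_z")) {
    spec <- config$prediction
    spec$feature_kind <- kind
    spec$rng_seed <- as.integer(.stage_seed(config$rng_seed,
                                            paste0("predict_", kind)))
    maps <- if (kind == "gbc") gbc_maps else fc_maps
    res <- loocv_predict(maps, subjects, spec)
    res <- permutation_test(maps, subjects, spec, res)
    out <- list(feature_kind = kind, strategy = strategy,
                r = res$r, mse = res$mse, p_r = res$p_r, p_mse = res$p_mse,
                n_perm = spec$n_perm, rng_seed = spec$rng_seed,
                predicted = res$predicted, observed = res$observed,
                modal_hyperparams = res$modal_hyperparams)
    jsonlite::write_json(out,
                         file.path(out_dir,
                                   paste0("prediction_", kind, ".json")),
                         auto_unbox = TRUE, digits = 10, pretty = TRUE)
    write_map(res$weight_map,
              file.path(out_dir, paste0("weights_", kind, ".nii")))
    write_cluster_table(res$clusters,
                        file.path(out_dir,
                                  paste0("weight_clusters_", kind, ".tsv")))
    predictions[[kind]] <- res
  }
  list(group = grp, predictions = predictions)
}

#' Run the full analysis pipeline
#'
#' Executes, per configured strategy: outlier detection and confound
#' assembly (from unsmoothed data), smoothing, the temporal denoising
#' chain, GBC and seed-FC maps per subject, the covariate-adjusted group
#' t-map with cluster-FWE inference on the seed-FC maps, and elastic-net
#' LOOCV prediction (with permutation p-values) for both feature kinds.
#' Every artifact directory receives a `provenance.json` with the config
#' echo, its MD5 hash and the derived stage seeds.
#'
#' @param config A `pipeline_config`.
#' @return A list with one element per strategy (`group`, `predictions`)
#'   plus `provenance`.
#' @export
run_pipeline <- function(config) {
  findings <- validate_config(config)
  errs <- findings$message[findings$severity == "error"]
  if (length(errs)) stop("invalid config:\n", paste("-", errs, collapse = "\n"))
  for (w in findings$message[findings$severity == "warning"]) warning(w)
  cohort <- read_cohort(config$cohort_dir)
  strategies <- if (config$denoise_strategy == "both")
    c("acompcor", "gsr") else config$denoise_strategy
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  cfg_json <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                               digits = 10, force = TRUE)
  cfg_file <- file.path(config$output_dir, "config_echo.json")
  writeLines(cfg_json, cfg_file)
  provenance <- list(config_md5 = unname(tools::md5sum(cfg_file)),
                     rng_seed = config$rng_seed,
                     stage_seeds = list(
                       group = .stage_seed(config$rng_seed, "group"),
                       predict_gbc = .stage_seed(config$rng_seed,
                                                 "predict_gbc"),
                       predict_seed_fc_z = .stage_seed(config$rng_seed,
                                                       "predict_seed_fc_z")),
                     strategies = strategies)
  jsonlite::write_json(provenance,
                       file.path(config$output_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  out <- list(provenance = provenance)
  for (strat in strategies) {
    out[[strat]] <- tryCatch(
      .run_strategy(cohort, config, strat,
                    file.path(config$output_dir, strat)),
      error = function(e) stop("pipeline stage failed under strategy '",
                               strat, "': ", conditionMessage(e),
                               call. = FALSE))
  }
  out
}
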