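# Run configuration and the command pipeline tying the modules together:
# simulate -> estimate-q -> reconstruct -> dose -> metrics, with validated
# unit-bearing configuration keys, a manifest recording provenance, and
# fail-fast cleanup of partial outputs.

# Allowed configuration schema: section -> keys. Every physical quantity
# carries its unit in the key name; unknown sections or keys are rejected.
run_config_schema <- function() {
  list(
    out_dir = NULL, seed = NULL, log_level = NULL,
    grid = c("dims", "spacing_mm"),
    object = c("baseline_magnitude", "semiaxes_frac"),
    tissue = c("density_kg_m3", "specific_heat_j_kg_c", "conductivity_w_m_c",
               "perfusion_kg_m3_s", "arterial_temp_c"),
    laser = c("peak_power_density_w_m3", "tip_position_mm", "orientation",
              "emitting_length_mm", "radial_decay_length_mm"),
    schedule = c("durations_s", "powers_w", "calibration_power_w"),
    acquisition = c("b0_tesla", "te_ms", "frame_interval_s"),
    noise = c("target_temp_precision_c", "complex_noise_sd"),
    sampling = c("scheme", "reduction_factor", "n_ky_trains", "train_length",
                 "center_width"),
    frames = c("n_frames", "calibration_dynamic"),
    crop = c("halfwidth_mm"),
    paths = c("series", "truth", "q", "recon", "diagnostics", "dose",
              "dose_mask", "metrics")
  )
}

config_error <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("mpftherm_config_error", "error")))
}

#' Validate a pipeline run configuration
#'
#' Checks the nested configuration list against the schema: unknown sections
#' or keys fail fast, every physical quantity carries explicit units in its
#' key name (`te_ms`, `b0_tesla`, `powers_w`, ...), and scalar sanity checks
#' (positive TE, field strength, spacings; consistent schedule lengths) are
#' applied. Defaults are filled for omitted optional keys.
#'
#' @param config named list, or a path to a JSON / YAML file holding one
#' @return validated configuration list of class `run_config`
#' @export
run_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) config_error("config file not found: %s", config)
    config <- if (grepl("\\.ya?ml$", config)) yaml::read_yaml(config)
    else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  if (inherits(config, "run_config")) return(config)
  if (!is.list(config)) config_error("config must be a named list or a file path")
  schema <- run_config_schema()
  unknown <- setdiff(names(config), names(schema))
  if (length(unknown))
    config_error("unknown config section(s): %s", paste(unknown, collapse = ", "))
  for (sec in names(config)) {
    keys <- schema[[sec]]
    if (is.null(keys)) next                      # scalar top-level key
    bad <- setdiff(names(config[[sec]]), keys)
    if (length(bad))
      config_error("unknown key(s) in '%s': %s", sec, paste(bad, collapse = ", "))
  }
  if (is.null(config$out_dir)) config_error("out_dir is required")
  if (is.null(config$seed)) config_error("seed is required")
  if (!is.numeric(config$seed) || config$seed != round(config$seed))
    config_error("seed must be an integer")
  config$log_level <- config$log_level %||% "info"
  if (!config$log_level %in% c("quiet", "info", "debug"))
    config_error("log_level must be quiet, info, or debug")

  if (!is.null(config$acquisition)) {
    a <- config$acquisition
    for (k in c("b0_tesla", "te_ms", "frame_interval_s"))
      if (is.null(a[[k]]) || !is.numeric(a[[k]]) || a[[k]] <= 0)
        config_error("acquisition$%s must be a positive number", k)
  }
  if (!is.null(config$grid)) {
    g <- config$grid
    if (is.null(g$dims) || !length(g$dims) %in% c(2L, 3L) || any(g$dims < 2))
      config_error("grid$dims must be 2 or 3 entries, each >= 2")
    if (is.null(g$spacing_mm) || any(g$spacing_mm <= 0))
      config_error("grid$spacing_mm must be positive")
  }
  if (!is.null(config$schedule)) {
    s <- config$schedule
    if (length(s$durations_s) != length(s$powers_w))
      config_error("schedule durations_s and powers_w must have equal length")
    if (any(s$durations_s <= 0) || any(s$powers_w < 0))
      config_error("schedule durations must be positive and powers nonnegative")
    if (is.null(s$calibration_power_w) || s$calibration_power_w <= 0)
      config_error("schedule$calibration_power_w must be positive")
  }
  if (!is.null(config$noise)) {
    has_t <- !is.null(config$noise$target_temp_precision_c)
    has_s <- !is.null(config$noise$complex_noise_sd)
    if (has_t == has_s)
      config_error("noise needs exactly one of target_temp_precision_c / complex_noise_sd")
  }
  if (!is.null(config$sampling)) {
    sc <- config$sampling$scheme %||% "none"
    if (!sc %in% c("none", "epi", "gaussian"))
      config_error("sampling$scheme must be none, epi, or gaussian")
    config$sampling$scheme <- sc
    config$sampling$reduction_factor <- config$sampling$reduction_factor %||% 1
  }
  # default artifact file names inside out_dir
  defaults <- c(series = "series.nii.gz", truth = "truth.nii.gz",
                q = "q.nii.gz", recon = "recon.nii.gz",
                diagnostics = "diagnostics.csv", dose = "dose.nii.gz",
                dose_mask = "dose_mask.nii.gz", metrics = "metrics.csv")
  paths <- config$paths %||% list()
  for (k in names(defaults)) paths[[k]] <- paths[[k]] %||% defaults[[k]]
  config$paths <- paths
  structure(config, class = c("run_config", "list"))
}

# Resolve an artifact path inside out_dir.
artifact_path <- function(config, key) file.path(config$out_dir, config$paths[[key]])

pipeline_log <- function(config, level, fmt, ...) {
  ranks <- c(quiet = 0, info = 1, debug = 2)
  if (ranks[[config$log_level]] >= ranks[[level]])
    message(sprintf(fmt, ...))
}

# Builders from validated config sections (required sections checked here so
# each command demands only what it uses).
need_section <- function(config, sec) {
  if (is.null(config[[sec]])) config_error("config section '%s' is required for this command", sec)
  config[[sec]]
}

config_props <- function(config) {
  t <- need_section(config, "tissue")
  tissue_properties(t$density_kg_m3, t$specific_heat_j_kg_c,
                    t$conductivity_w_m_c,
                    perfusion_kg_m3_s = t$perfusion_kg_m3_s %||% 0,
                    arterial_temp_c = t$arterial_temp_c %||% 37)
}

config_acq <- function(config) {
  a <- need_section(config, "acquisition")
  acquisition_params(b0_t = a$b0_tesla, te_s = a$te_ms / 1000,
                     frame_interval_s = a$frame_interval_s)
}

config_schedule <- function(config) {
  s <- need_section(config, "schedule")
  power_schedule(s$durations_s, s$powers_w,
                 calibration_power_w = s$calibration_power_w)
}

config_phantom <- function(config) {
  g <- need_section(config, "grid")
  o <- config$object %||% list()
  phantom_spec(g$dims, g$spacing_mm,
               baseline_magnitude = o$baseline_magnitude %||% 100,
               props = config_props(config),
               object_semiaxes_frac = o$semiaxes_frac %||% 1)
}

config_laser <- function(config) {
  l <- need_section(config, "laser")
  laser_spec(l$peak_power_density_w_m3, tip_position_mm = l$tip_position_mm,
             orientation = l$orientation,
             emitting_length_mm = l$emitting_length_mm %||% 10,
             radial_decay_length_mm = l$radial_decay_length_mm %||% 3)
}

config_mask <- function(config, n_lines, frame_index) {
  s <- config$sampling %||% list(scheme = "none")
  R <- as.integer(s$reduction_factor %||% 1)
  switch(s$scheme,
    none = NULL,
    epi = {
      trains <- as.integer(s$n_ky_trains %||% n_lines)
      tl <- as.integer(s$train_length %||% (n_lines / trains))
      if (trains * tl != n_lines)
        config_error("n_ky_trains * train_length must equal the line count %d", n_lines)
      epi_mask(trains, R, frame_index = frame_index, train_length = tl)
    },
    gaussian = gaussian_mask(n_lines, R,
                             center_width = s$center_width %||% 20L,
                             seed = config$seed * 10000L + frame_index,
                             frame_index = frame_index))
}

# Canonical config hash for the manifest: md5 of the sorted-key JSON.
config_hash <- function(config) {
  canon <- function(x) {
    if (is.list(x)) lapply(x[order(names(x))], canon) else x
  }
  js <- jsonlite::toJSON(canon(unclass(config)), auto_unbox = TRUE, digits = NA)
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(as.character(js), tmp)
  unname(tools::md5sum(tmp))
}

write_manifest <- function(config, command, artifacts) {
  manifest <- list(
    command = command,
    seed = config$seed,
    config_hash = config_hash(config),
    config = unclass(config),
    artifacts = artifacts,
    versions = list(
      r = R.version.string,
      package = tryCatch(as.character(utils::packageVersion("mpftherm")),
                         error = function(e) "unversioned")
    )
  )
  path <- file.path(config$out_dir, sprintf("manifest_%s.json", command))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  path
}

#' Run one pipeline command
#'
#' Commands: `"simulate"` (digital phantom heating: truth temperatures,
#' complex dynamics, generating Q), `"estimate-q"` (deposited-power map from
#' the calibration dynamics), `"reconstruct"` (retrospective subsampling per
#' the sampling config, then model predictive filtering; `reduction_factor 1`
#' or scheme `"none"` gives the direct fully sampled reconstruction),
#' `"dose"` (CEM43 map and 240-min ablation mask from a temperature series),
#' and `"metrics"` (truth-vs-reconstruction comparison table). Each command
#' writes its artifacts into `out_dir` plus a manifest JSON recording the
#' command, seed, config hash, and package versions. On any error, artifacts
#' created by the failed command are removed before the error propagates.
#'
#' @param config [run_config()], a named list, or a JSON/YAML file path
#' @param command one of `"simulate"`, `"estimate-q"`, `"reconstruct"`,
#'   `"dose"`, `"metrics"`
#' @return named list of artifact paths (including `manifest`), invisibly
#' @export
run_pipeline <- function(config,
                         command = c("simulate", "estimate-q", "reconstruct",
                                     "dose", "metrics")) {
  command <- match.arg(command)
  config <- run_config(config)
  if (!dir.exists(config$out_dir))
    dir.create(config$out_dir, recursive = TRUE)
  created <- character(0)
  note <- function(path) { created <<- c(created, path, paste0(path, ".json")); path }
  artifacts <- tryCatch({
    switch(command,
      simulate = {
        phantom <- config_phantom(config)
        laser <- config_laser(config)
        schedule <- config_schedule(config)
        acq <- config_acq(config)
        noise <- c(need_section(config, "noise"), list(seed = config$seed))
        nf <- need_section(config, "frames")$n_frames
        pipeline_log(config, "info", "simulate: %s grid, %d frames",
                     paste(phantom$dims, collapse = "x"), nf)
        sim <- simulate_experiment(phantom, laser, schedule, acq, noise, nf)
        list(
          truth = note(write_temperature_nifti(sim$truth,
                                               artifact_path(config, "truth"))),
          series = note(write_complex_series(sim$frames,
                                             artifact_path(config, "series"),
                                             phantom$spacing_mm,
                                             acq$frame_interval_s)),
          q = note(write_qmap_nifti(sim$q, artifact_path(config, "q")))
        )
      },
      `estimate-q` = {
        ser <- read_complex_series(artifact_path(config, "series"))
        props <- config_props(config)
        schedule <- config_schedule(config)
        acq <- config_acq(config)
        dyn <- (config$frames %||% list())$calibration_dynamic %||% 1L
        rec <- prf_reconstruct(ser$frames, acq, ser$spacing_mm)
        crop <- NULL
        if (!is.null(config$crop$halfwidth_mm)) {
          phantom <- config_phantom(config)
          crop <- applicator_crop_roi(phantom, config_laser(config),
                                      config$crop$halfwidth_mm)
        }
        pipeline_log(config, "info", "estimate-q: dynamic %d", dyn)
        q <- estimate_q(rec, props, schedule, dynamic_index = dyn,
                        crop_roi = crop)
        pipeline_log(config, "info", "estimate-q: scale factor %.4g",
                     q$provenance$scale_factor)
        list(q = note(write_qmap_nifti(q, artifact_path(config, "q"))))
      },
      reconstruct = {
        ser <- read_complex_series(artifact_path(config, "series"))
        q <- read_qmap_nifti(artifact_path(config, "q"))
        cfg <- mpf_config(config_props(config), config_acq(config), q,
                          config_schedule(config))
        kspace <- lapply(ser$frames, image_to_kspace)
        n_lines <- dim(ser$frames[[1L]]$data)[2L]
        for (n in seq_along(kspace)[-1L]) {
          m <- config_mask(config, n_lines, frame_index = n - 2L)
          if (!is.null(m)) kspace[[n]] <- subsample_kspace(kspace[[n]], m)
        }
        res <- mpf_reconstruct(kspace, cfg)
        for (i in seq_len(nrow(res$diagnostics)))
          pipeline_log(config, "debug",
                       "frame %d: model fraction %.2f, hottest %.2f degC, max step phase %.2f rad",
                       res$diagnostics$frame[i], res$diagnostics$model_fraction[i],
                       res$diagnostics$hottest_c[i],
                       res$diagnostics$max_step_phase_rad[i])
        pipeline_log(config, "info", "reconstruct: peak dT %.2f degC",
                     max(res$temperature$frames))
        list(
          recon = note(write_temperature_nifti(res$temperature,
                                               artifact_path(config, "recon"))),
          diagnostics = note(write_table_csv(res$diagnostics,
                                             artifact_path(config, "diagnostics")))
        )
      },
      dose = {
        series <- read_temperature_nifti(artifact_path(config, "recon"))
        d <- cem43(series)
        m <- dose_mask(d)
        pipeline_log(config, "info", "dose: %d voxels >= 240 CEM43", sum(m))
        dpath <- artifact_path(config, "dose")
        img <- RNifti::asNifti(d$cem43)
        img <- RNifti::`pixdim<-`(img, d$spacing_mm)
        RNifti::writeNifti(img, dpath)
        list(dose = note(dpath),
             dose_mask = note(write_mask_nifti(m, artifact_path(config, "dose_mask"),
                                               d$spacing_mm)))
      },
      metrics = {
        truth <- read_temperature_nifti(artifact_path(config, "truth"))
        recon <- read_temperature_nifti(artifact_path(config, "recon"))
        dsc <- dice(dose_mask(cem43(truth)), dose_mask(cem43(recon)))
        cm <- curve_metrics(hottest_curve(truth), hottest_curve(recon))
        df <- data.frame(dsc = as.numeric(dsc), rmse = cm$rmse,
                         max_abs_diff = cm$max_abs_diff,
                         t_test_p = cm$t_test_p)
        pipeline_log(config, "info", "metrics: dsc %.3f, rmse %.4g degC",
                     df$dsc, df$rmse)
        list(metrics = note(write_table_csv(df, artifact_path(config, "metrics"))))
      }
    )
  }, error = function(e) {
    unlink(created[file.exists(created)])
    stop(e)
  })
  artifacts$manifest <- write_manifest(config, command, artifacts)
  invisible(artifacts)
}
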