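# Assay orchestration: configuration validation and end-to-end runs.
#
# A run configuration describes one assay (global-stimulation kinetics,
# center-stimulation spatial spread, or migration statistics) over
# synthetic scenes or on-disk stacks. Stages run in a fixed order
# (corrections -> alignment -> segmentation/tracking -> bleach correction
# where applicable -> ratio -> assay analysis); every QC rejection is
# recorded with its reason, and rejected + included counts reconcile with
# detected counts.

#' Validate and normalize a run configuration
#'
#' Fills defaults, checks units and ranges, and reports all problems at
#' once. Normalization is idempotent.
#'
#' @param config named list (e.g. parsed from YAML).
#' @return normalized config list with attribute `errors` = character();
#'   on any problem, throws unless `stop_on_error = FALSE`, in which case
#'   the error vector is attached.
#' @param stop_on_error throw on validation errors (default TRUE).
#' @export
validate_config <- function(config, stop_on_error = TRUE) {
  errors <- character()
  req <- function(field, default = NULL, check = NULL, msg = NULL) {
    if (is.null(config[[field]])) {
      if (is.null(default)) {
        errors <<- c(errors, sprintf("missing required field: %s", field))
        return(invisible(NULL))
      }
      config[[field]] <<- default
    }
    if (!is.null(check) && !is.null(config[[field]]) &&
        !isTRUE(check(config[[field]])))
      errors <<- c(errors, msg %||% sprintf("invalid value for field: %s", field))
    invisible(NULL)
  }
  req("assay", check = function(a) a %in% c("global", "center", "migration"),
      msg = "assay must be one of global, center, migration")
  req("seed", default = 1L,
      check = function(s) is.numeric(s) && s == round(s))
  req("out_dir")
  req("pixel_size", default = 0.325, check = function(p) p > 0,
      msg = "pixel_size must be > 0")
  req("frame_interval", default = 1.5, check = function(f) f > 0,
      msg = "frame_interval must be > 0")
  req("field_shape", default = c(160L, 160L),
      check = function(f) length(f) == 2 && all(f >= 16))
  req("n_frames", default = 26L, check = function(n) n >= 1)
  req("n_cells", default = 8L, check = function(n) n >= 0)
  req("cell_radius", default = 4, check = function(r) r > 0)
  req("dead_fraction", default = 0, check = function(x) x >= 0 && x <= 1)
  req("use_noise", default = TRUE)
  req("min_area", default = 80, check = function(x) x > 0)
  req("max_area", default = 2000, check = function(x) x > 0)
  req("max_link_um", default = 10, check = function(x) x > 0)
  if (identical(config$assay, "global")) {
    req("doses", default = c(0, 3, 6, 10),
        check = function(d) all(d >= 0),
        msg = "doses must be non-negative percent amplitudes")
    req("stim_time", default = 15, check = function(t) t > 0)
  }
  if (identical(config$assay, "center")) {
    req("stim_log", msg = "center assay requires a stimulus log (stim_log)")
    req("bleach", default = list(b0 = 0.3, sigma0 = 1.5, D = 0.5,
                                 alpha = 1, calibration_power = 37))
  }
  if (identical(config$assay, "migration")) {
    req("n_tracks", default = 200L, check = function(n) n >= 1)
    req("track_mode", default = "persistent",
        check = function(m) m %in% c("ballistic", "brownian", "persistent"))
    req("interval_s", default = 30, check = function(x) x > 0)
    req("min_net_um", default = 5, check = function(x) x >= 0)
  }
  config$field_shape <- as.integer(config$field_shape)
  config$seed <- as.integer(config$seed)
  attr(config, "errors") <- errors
  if (length(errors) && stop_on_error)
    stop("invalid configuration:\n  ", paste(errors, collapse = "\n  "))
  config
}

#' Read a YAML run configuration
#' @param path YAML file.
#' @return validated config list.
#' @export
read_config <- function(path) {
  validate_config(yaml::read_yaml(path))
}

#' Run a configured assay end to end
#'
#' Deterministic for a fixed config + seed. Outputs are written as CSV
#' under `config$out_dir` together with a JSON QC log; partial outputs
#' are never left behind on error (written to a temporary directory and
#' moved on success).
#'
#' @param config validated configuration (see [validate_config()]).
#' @return list with the result tables and a `qc` list; CSV paths in
#'   `files`.
#' @export
run_assay <- function(config) {
  config <- validate_config(config)
  tmp <- tempfile("optofret_run_")
  dir.create(tmp, recursive = TRUE)
  res <- switch(config$assay,
                global = .run_global(config, tmp),
                center = .run_center(config, tmp),
                migration = .run_migration(config, tmp))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- list.files(tmp, full.names = TRUE)
  ok <- file.copy(files, config$out_dir, overwrite = TRUE)
  unlink(tmp, recursive = TRUE)
  res$files <- file.path(config$out_dir, basename(files))[ok]
  jsonlite::write_json(res$qc,
                       file.path(config$out_dir, "qc_log.json"),
                       auto_unbox = TRUE, digits = NA)
  res
}

.write_csv_canonical <- function(df, path) {
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(v) signif(v, 12))
  utils::write.csv(df, path, row.names = FALSE)
}

.run_global <- function(config, out) {
  fs <- config$field_shape
  series_all <- list(); fc_all <- list(); qc <- list()
  for (dose in config$doses) {
    seed <- derive_seed(config$seed, round(100 * dose))
    sp <- scene_params(
      field_shape = fs, pixel_size = config$pixel_size,
      frame_interval = config$frame_interval, n_frames = config$n_frames,
      n_cells = config$n_cells, dead_fraction = config$dead_fraction,
      cell_radius = config$cell_radius, speed = 0.02,
      programmed_amplitude = dose / 100,
      stimuli = list(stimulus_event(config$stim_time, "global", power = 1)))
    scene <- make_scene(sp, seed)
    optics <- optics_model(fs, vignette_strength = 0.01,
                           half_chip_factor = 0.99, dust = NULL,
                           bg_level = 400)
    stack <- render_frames(scene, optics, noise = config$use_noise)
    dark <- matrix(optics$dark_offset, fs[1], fs[2])
    corr <- correction_set(dark, dark)
    sums <- lapply(seq_len(config$n_frames), function(fr)
      apply_corrections(stack$donor[[fr]], "donor", corr) +
        apply_corrections(stack$acceptor[[fr]], "acceptor", corr))
    bg <- estimate_background(sums, "dense",
                              empty_profile = 2 * .background_field(optics))
    labels <- lapply(sums, function(s)
      segment_cells(s - bg$background, config$min_area, config$max_area))
    tracks <- track_cells(labels, config$pixel_size, config$max_link_um)
    rframes <- ratio_frames(stack, corr,
                            background = list(
                              donor = bg$background / 2,
                              acceptor = bg$background / 2))
    series <- population_timeseries(stack, corrections = corr,
                                    background = list(
                                      donor = bg$background / 2,
                                      acceptor = bg$background / 2))
    series$dose <- dose
    series_all[[length(series_all) + 1]] <- series
    fc <- single_cell_fold_change(tracks, rframes, labels, stack$times,
                                  stim_time = config$stim_time)
    fc$dose <- dose
    fc_all[[length(fc_all) + 1]] <- fc
    qc[[paste0("dose_", dose)]] <- list(
      n_detected = length(unique(tracks$track)),
      n_included = sum(fc$included),
      n_excluded = sum(!fc$included),
      excluded_reasons = as.list(table(fc$reason[!fc$included])),
      n_dead_planted = sum(vapply(scene$cells, function(c) c$is_dead, TRUE)))
  }
  series_all <- do.call(rbind, series_all)
  fc_all <- do.call(rbind, fc_all)
  .write_csv_canonical(series_all, file.path(out, "well_series.csv"))
  .write_csv_canonical(fc_all, file.path(out, "fold_changes.csv"))
  list(series = series_all, fold_changes = fc_all, qc = qc)
}

.run_center <- function(config, out) {
  fs <- config$field_shape
  log <- config$stim_log
  if (is.character(log)) log <- read_stim_log(log)
  log <- as.data.frame(log)
  stim <- stimulus_event(log$t_s[1], "focal", power = log$power_uW[1],
                         target = c(log$target_col[1], log$target_row[1]))
  bm <- do.call(bleach_model, config$bleach)
  sp <- scene_params(field_shape = fs, pixel_size = config$pixel_size,
                     frame_interval = config$frame_interval,
                     n_frames = config$n_frames, n_cells = 1,
                     cell_radius = min(fs) * config$pixel_size / 3,
                     speed = 0, sensor_density = 8000,
                     stimuli = list(stim))
  scene <- make_scene(sp, config$seed)
  optics <- identity_optics(fs)
  stack <- render_bleach(scene, optics, bm, noise = config$use_noise)
  masks <- lapply(seq_len(config$n_frames), function(fr)
    scene_cell_mask(scene, 1, fr))
  rframes <- ratio_frames(stack, smooth_sigma = 0)
  pre_frame <- max(which(stack$times < stim$time))
  rcorr <- correct_ratio_series(rframes, bm, list(stim), stack$times,
                                config$pixel_size)
  don <- lapply(seq_len(config$n_frames), function(fr) stack$donor[[fr]])
  acc <- lapply(seq_len(config$n_frames), function(fr) {
    # fold the bleach-corrected ratio back into an acceptor-equivalent
    rcorr[[fr]]$ratio * stack$donor[[fr]]
  })
  prof <- radial_profile(don, acc, masks, stim$target, pre_frame,
                         config$pixel_size)
  .write_csv_canonical(prof, file.path(out, "radial_profile.csv"))
  qc <- list(n_cells = 1, pre_frame = pre_frame)
  list(profile = prof, qc = qc)
}

.run_migration <- function(config, out) {
  tracks <- simulate_tracks(config$n_tracks, interval = config$interval_s,
                            mode = config$track_mode, seed = config$seed)
  msd <- mean_squared_displacement(tracks, min_net = config$min_net_um)
  pc <- persistence_cosine(tracks, min_first_step = config$min_net_um)
  .write_csv_canonical(msd, file.path(out, "msd.csv"))
  .write_csv_canonical(pc, file.path(out, "persistence_cosine.csv"))
  list(msd = msd, cosine = pc,
       qc = list(n_tracks = config$n_tracks,
                 n_msd_cells = msd$n_cells[1],
                 n_cos_cells = pc$n_cells[1]))
}
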