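# Stack and ground-truth persistence.
#
# Image stacks are written as one multi-page 16-bit TIFF per channel
# (frame-major) with a JSON sidecar holding pixel size, frame interval,
# stimulus log, and (for synthetic scenes) the ground truth summary and
# configuration echo.

#' Write a dual-channel stack to disk
#'
#' @param stack `fret_stack`.
#' @param dir output directory (created if needed).
#' @param name base name for the files.
#' @param scene optional `fret_scene`; its ground truth summary is stored
#'   in the sidecar.
#' @return invisibly, the sidecar path.
#' @export
write_stack <- function(stack, dir, name = "stack", scene = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  maxv <- 2^stack$bit_depth - 1
  to01 <- function(frames) lapply(frames, function(f)
    pmin(pmax(f / maxv, 0), 1))
  tiff::writeTIFF(to01(stack$donor),
                  file.path(dir, paste0(name, "_donor.tif")),
                  bits.per.sample = 16L)
  tiff::writeTIFF(to01(stack$acceptor),
                  file.path(dir, paste0(name, "_acceptor.tif")),
                  bits.per.sample = 16L)
  meta <- list(
    name = name, n_frames = length(stack$donor),
    field_shape = stack$field_shape, pixel_size = stack$pixel_size,
    frame_interval = stack$frame_interval, times = stack$times,
    bit_depth = stack$bit_depth,
    stimuli = lapply(stack$stimuli, unclass))
  if (!is.null(scene)) {
    meta$ground_truth <- list(
      seed = scene$seed, amp_eff = scene$amp_eff,
      n_cells = length(scene$cells),
      cells = lapply(scene$cells, function(cl) list(
        is_dead = cl$is_dead, baseline_ratio = cl$baseline_ratio,
        centroids_um = cl$centroids,
        mean_activity = vapply(cl$activity, mean, 0))))
    meta$config_echo <- unclass(scene$params)
    meta$config_echo$kinetics <- unclass(meta$config_echo$kinetics)
    meta$config_echo$stimuli <- lapply(meta$config_echo$stimuli, unclass)
  }
  sidecar <- file.path(dir, paste0(name, "_meta.json"))
  jsonlite::write_json(meta, sidecar, auto_unbox = TRUE, digits = NA,
                       null = "null", matrix = "rowmajor")
  invisible(sidecar)
}

#' Read a dual-channel stack written by [write_stack()]
#'
#' @param dir directory.
#' @param name base name.
#' @return `fret_stack` (counts restored to the stored bit depth).
#' @export
read_stack <- function(dir, name = "stack") {
  meta <- jsonlite::read_json(file.path(dir, paste0(name, "_meta.json")),
                              simplifyVector = TRUE)
  maxv <- 2^meta$bit_depth - 1
  rd <- function(ch) {
    frames <- tiff::readTIFF(file.path(dir, paste0(name, "_", ch, ".tif")),
                             all = TRUE)
    lapply(frames, function(f) round(f * maxv))
  }
  stims <- list()
  if (length(meta$stimuli)) {
    sl <- meta$stimuli
    if (is.data.frame(sl)) sl <- split(sl, seq_len(nrow(sl)))
    stims <- lapply(sl, function(s)
      stimulus_event(s$time, s$kind, s$power,
                     target = if (!is.null(s$target) &&
                                  length(unlist(s$target)) == 2)
                       unlist(s$target) else NULL,
                     duration = s$duration %||% 0.010))
  }
  structure(list(donor = rd("donor"), acceptor = rd("acceptor"),
                 times = as.numeric(meta$times),
                 pixel_size = meta$pixel_size,
                 frame_interval = meta$frame_interval,
                 stimuli = stims,
                 field_shape = as.integer(meta$field_shape),
                 bit_depth = as.integer(meta$bit_depth)),
            class = "fret_stack")
}

#' Write / read a stimulus and stage log as CSV
#'
#' Columns: frame, t_s, event, power_uW, target_row, target_col,
#' stage_dx_um, stage_dy_um.
#'
#' @param log data.frame in the column layout above.
#' @param path CSV path.
#' @export
write_stim_log <- function(log, path) {
  utils::write.csv(log, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_stim_log
#' @export
read_stim_log <- function(path) {
  utils::read.csv(path)
}
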