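# FRET ratio computation and stimulus-response kinetics.
#
# Ratios are acceptor/donor after channel corrections, alignment, and
# background subtraction. Pixel filters invalidate dim, near-saturating,
# and low-ratio (< 0.8, dead/unhealthy cell) pixels. Population series use
# the ratio of channel means (not the mean of pixel ratios), normalized by
# the pre-stimulus mean; single-cell responses are summarized as window
# fold changes around the stimulus.

# reason codes for invalid pixels
RATIO_REASONS <- c(valid = 0L, out_of_mask = 1L, dim = 2L, saturated = 3L,
                   low_ratio = 4L, unmapped = 5L)

#' Pixel filter thresholds for ratio images
#'
#' @param dim_frac dim-pixel threshold as a fraction of the bit-depth
#'   range, applied to the background-subtracted donor (default 0.02).
#' @param sat_frac near-saturation threshold as a fraction of the
#'   bit-depth range (default 0.98).
#' @param low_ratio dead/unhealthy pixel threshold on the ratio (default
#'   0.8).
#' @param bit_depth camera bit depth (default 16).
#' @return list of class `fret_filters`.
#' @export
ratio_filters <- function(dim_frac = 0.02, sat_frac = 0.98,
                          low_ratio = 0.8, bit_depth = 16L) {
  structure(list(dim_frac = dim_frac, sat_frac = sat_frac,
                 low_ratio = low_ratio, bit_depth = as.integer(bit_depth)),
            class = "fret_filters")
}

#' Compute a quality-filtered ratio image
#'
#' The donor must already be aligned into acceptor coordinates. Both
#' channels are background subtracted and smoothed (Gaussian sigma 1 by
#' default); the ratio is acceptor/donor, divided by the ratio-correction
#' image. Pixels are invalidated (with a reason code) when outside the
#' mask, unmapped by the alignment, dim, near saturating, or of low ratio.
#' A zero or negative donor never produces an infinity: the pixel is
#' invalidated as dim.
#'
#' @param donor,acceptor corrected images (donor aligned).
#' @param mask logical cell mask (NULL = whole field).
#' @param corrections `fret_corrections` (supplies the ratio-correction
#'   image); NULL for none.
#' @param background_donor,background_acceptor background images or
#'   scalars subtracted before smoothing.
#' @param smooth_sigma Gaussian sigma (px, default 1; 0 disables).
#' @param filters `fret_filters`.
#' @return object of class `fret_ratio_frame`: list with `ratio` (matrix,
#'   `NA` at invalid pixels) and `reason` (integer matrix of
#'   `RATIO_REASONS` codes).
#' @export
compute_ratio_image <- function(donor, acceptor, mask = NULL,
                                corrections = NULL,
                                background_donor = 0,
                                background_acceptor = 0,
                                smooth_sigma = 1,
                                filters = ratio_filters()) {
  stopifnot(all(dim(donor) == dim(acceptor)))
  d <- dim(donor)
  if (is.null(mask)) mask <- matrix(TRUE, d[1], d[2])
  rng <- 2^filters$bit_depth - 1
  reason <- matrix(RATIO_REASONS[["valid"]], d[1], d[2])
  reason[!mask] <- RATIO_REASONS[["out_of_mask"]]
  unmapped <- is.na(donor) | is.na(acceptor)
  reason[unmapped & reason == 0L] <- RATIO_REASONS[["unmapped"]]
  sat <- !unmapped & (donor >= filters$sat_frac * rng |
                        acceptor >= filters$sat_frac * rng)
  reason[sat & reason == 0L] <- RATIO_REASONS[["saturated"]]
  don <- donor - background_donor
  acc <- acceptor - background_acceptor
  don[unmapped] <- 0; acc[unmapped] <- 0
  if (smooth_sigma > 0) {
    don <- gauss_smooth(don, smooth_sigma)
    acc <- gauss_smooth(acc, smooth_sigma)
  }
  dim_px <- don <= filters$dim_frac * rng
  reason[dim_px & reason == 0L] <- RATIO_REASONS[["dim"]]
  ratio <- matrix(NA_real_, d[1], d[2])
  ok <- reason == 0L
  ratio[ok] <- acc[ok] / don[ok]
  if (!is.null(corrections))
    ratio <- ratio / corrections$ratio_correction
  low <- !is.na(ratio) & ratio < filters$low_ratio
  reason[low & reason == 0L] <- RATIO_REASONS[["low_ratio"]]
  ratio[reason != 0L] <- NA_real_
  structure(list(ratio = ratio, reason = reason),
            class = "fret_ratio_frame")
}

#' Ratio frames for every frame of a stack
#'
#' Applies channel corrections, donor alignment, and
#' [compute_ratio_image()] per frame.
#'
#' @param stack `fret_stack`.
#' @param corrections `fret_corrections`.
#' @param alignment `fret_alignment` (identity if NULL).
#' @param background list with `donor`, `acceptor` background images or
#'   scalars.
#' @param masks optional list of per-frame logical masks.
#' @param smooth_sigma,filters passed to [compute_ratio_image()].
#' @return list of `fret_ratio_frame`.
#' @export
ratio_frames <- function(stack, corrections = NULL, alignment = NULL,
                         background = list(donor = 0, acceptor = 0),
                         masks = NULL, smooth_sigma = 1,
                         filters = ratio_filters()) {
  fs <- stack$field_shape
  if (is.null(corrections)) corrections <- identity_corrections(fs)
  lapply(seq_along(stack$donor), function(fr) {
    don <- apply_corrections(stack$donor[[fr]], "donor", corrections)
    acc <- apply_corrections(stack$acceptor[[fr]], "acceptor", corrections)
    if (!is.null(alignment)) don <- apply_alignment(don, alignment)
    compute_ratio_image(don, acc, mask = masks[[fr]] %||% NULL,
                        corrections = corrections,
                        background_donor = background$donor,
                        background_acceptor = background$acceptor,
                        smooth_sigma = smooth_sigma, filters = filters)
  })
}

#' Population (well-level) response time series
#'
#' Per frame, the mean valid donor and mean valid acceptor are computed
#' first and their quotient taken (ratio of means). The series is
#' normalized by the mean of the pre-stimulus time points and the time
#' axis is expressed relative to the last frame before stimulation.
#'
#' @param stack `fret_stack` for one well.
#' @param stim_time stimulation time (s); defaults to the first stimulus
#'   in the stack metadata.
#' @param corrections,alignment,background,masks,smooth_sigma,filters as
#'   in [ratio_frames()].
#' @return data.frame with `time` (s, relative), `ratio` (raw ratio of
#'   means), `ratio_norm`, `n_valid`; frames with no valid pixels carry
#'   `NA`, never zero.
#' @export
population_timeseries <- function(stack, stim_time = NULL,
                                  corrections = NULL, alignment = NULL,
                                  background = list(donor = 0, acceptor = 0),
                                  masks = NULL, smooth_sigma = 1,
                                  filters = ratio_filters()) {
  if (is.null(stim_time)) {
    st <- vapply(stack$stimuli, function(s) s$time, 0)
    if (length(st) == 0) stop("no stimulus time available")
    stim_time <- min(st)
  }
  fs <- stack$field_shape
  if (is.null(corrections)) corrections <- identity_corrections(fs)
  vals <- lapply(seq_along(stack$donor), function(fr) {
    don <- apply_corrections(stack$donor[[fr]], "donor", corrections)
    acc <- apply_corrections(stack$acceptor[[fr]], "acceptor", corrections)
    if (!is.null(alignment)) don <- apply_alignment(don, alignment)
    rf <- compute_ratio_image(don, acc, mask = masks[[fr]] %||% NULL,
                              corrections = corrections,
                              background_donor = background$donor,
                              background_acceptor = background$acceptor,
                              smooth_sigma = smooth_sigma,
                              filters = filters)
    ok <- rf$reason == 0L
    don_s <- don - background$donor
    acc_s <- acc - background$acceptor
    if (!any(ok)) return(c(NA_real_, 0))
    # ratio of means over valid pixels, with the ratio correction applied
    # as the mean correction over the same pixels
    rc_mean <- mean(corrections$ratio_correction[ok])
    c(mean(acc_s[ok]) / mean(don_s[ok]) / rc_mean, sum(ok))
  })
  ratio <- vapply(vals, `[`, 0, 1)
  n_valid <- vapply(vals, `[`, 0, 2)
  pre <- stack$times < stim_time
  if (!any(pre)) stop("need at least one pre-stimulus frame")
  t0 <- max(stack$times[pre])
  norm <- mean(ratio[pre], na.rm = TRUE)
  data.frame(time = stack$times - t0, ratio = ratio,
             ratio_norm = ratio / norm, n_valid = n_valid)
}

#' Standard response windows
#'
#' Two control windows before the stimulus and one peak window after it,
#' each spanning five frames at 1.5 s spacing. Times are relative to the
#' last pre-stimulus frame.
#'
#' @param c1,c2,p closed intervals c(lo, hi) in seconds.
#' @return list of class `fret_windows`.
#' @export
response_windows <- function(c1 = c(-13.5, -7.5), c2 = c(-6, 0),
                             p = c(4.5, 10.5)) {
  w <- list(c1 = c1, c2 = c2, p = p)
  if (!(c1[2] < c2[1] && c2[2] < p[1]))
    stop("windows must be ordered and non-overlapping")
  class(w) <- "fret_windows"
  w
}

#' Single-cell response fold changes
#'
#' For every complete track, the per-frame cell ratio (ratio of means
#' over the cell's valid pixels) is averaged within each response window;
#' the peak fold change is P/C2 and the control fold change C1/C2. Cells
#' are excluded (with a reason) when their track is incomplete, their
#' baseline ratio over the first `baseline_frames` frames is below
#' `baseline_min` (dead-cell rule), any pixel of the cell is saturated in
#' either channel at any frame, or a window lacks frames.
#'
#' @param tracks track table from [track_cells()].
#' @param rframes list of `fret_ratio_frame`.
#' @param label_stack list of label matrices matching `rframes`.
#' @param times frame times (s).
#' @param stim_time stimulation time (s); window positions are relative
#'   to the last frame before it.
#' @param windows `fret_windows`.
#' @param baseline_frames,baseline_min dead-cell screen (defaults 10
#'   frames, 0.95).
#' @return data.frame with one row per track: `track`, `p_c2`, `c1_c2`,
#'   `included`, `reason`, `baseline`.
#' @export
single_cell_fold_change <- function(tracks, rframes, label_stack, times,
                                    stim_time, windows = response_windows(),
                                    baseline_frames = 10,
                                    baseline_min = 0.95) {
  t0 <- max(times[times < stim_time])
  rel <- times - t0
  out <- list()
  for (tr in sort(unique(tracks$track))) {
    rows <- tracks[tracks$track == tr, ]
    res <- list(track = tr, p_c2 = NA_real_, c1_c2 = NA_real_,
                included = FALSE, reason = "", baseline = NA_real_)
    if (!all(rows$complete)) {
      res$reason <- "incomplete_track"
      out[[length(out) + 1]] <- res; next
    }
    series <- rep(NA_real_, length(times))
    saturated <- FALSE
    for (k in seq_len(nrow(rows))) {
      fr <- rows$frame[k]
      sel <- label_stack[[fr]] == rows$label[k]
      if (any(rframes[[fr]]$reason[sel] == RATIO_REASONS[["saturated"]]))
        saturated <- TRUE
      v <- rframes[[fr]]$ratio[sel]
      if (any(is.finite(v))) series[fr] <- mean(v[is.finite(v)])
    }
    if (saturated) {
      res$reason <- "saturated_pixels"
      out[[length(out) + 1]] <- res; next
    }
    nb <- min(baseline_frames, sum(rel <= 0))
    res$baseline <- mean(series[seq_len(nb)], na.rm = TRUE)
    if (!is.finite(res$baseline) || res$baseline < baseline_min) {
      res$reason <- "low_baseline"
      out[[length(out) + 1]] <- res; next
    }
    wmean <- function(w) {
      inw <- rel >= w[1] & rel <= w[2]
      if (!any(inw) || any(is.na(series[inw]))) NA_real_
      else mean(series[inw])
    }
    mC1 <- wmean(windows$c1); mC2 <- wmean(windows$c2); mP <- wmean(windows$p)
    if (any(is.na(c(mC1, mC2, mP)))) {
      res$reason <- "missing_window_frames"
      out[[length(out) + 1]] <- res; next
    }
    res$p_c2 <- mP / mC2
    res$c1_c2 <- mC1 / mC2
    res$included <- TRUE
    out[[length(out) + 1]] <- res
  }
  do.call(rbind, lapply(out, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
}

#' Mean response histogram across experiments
#'
#' Relative-frequency histograms of per-cell fold changes on shared bin
#' edges, averaged across experiment groups with the SEM per bin.
#'
#' @param groups named list of numeric vectors (one per experiment).
#' @param breaks bin edges (default 40 bins over [0.9, 1.4]).
#' @return data.frame with `mid`, `mean`, `sem`, `n_groups`.
#' @export
response_histograms <- function(groups, breaks = seq(0.9, 1.4,
                                                     length.out = 41)) {
  keep <- vapply(groups, function(g) length(g) > 0, TRUE)
  if (any(!keep)) warning("dropping empty experiment group(s)")
  groups <- groups[keep]
  if (length(groups) < 1) stop("no non-empty groups")
  H <- vapply(groups, function(g) {
    h <- graphics::hist(pmin(pmax(g, breaks[1]), breaks[length(breaks)]),
                        breaks = breaks, plot = FALSE)
    h$counts / sum(h$counts)
  }, numeric(length(breaks) - 1))
  H <- matrix(H, nrow = length(breaks) - 1)
  m <- rowMeans(H)
  sem <- if (ncol(H) > 1) apply(H, 1, stats::sd) / sqrt(ncol(H)) else
    rep(NA_real_, nrow(H))
  data.frame(mid = (breaks[-1] + breaks[-length(breaks)]) / 2,
             mean = m, sem = sem, n_groups = ncol(H))
}

#' Relative amplitude of the second response peak
#'
#' For a two-pulse experiment, the response amplitude of each pulse is
#' max(series - 1) within `window` seconds after the pulse (on the
#' pre-stimulus-normalized series). Returns amplitude2/amplitude1. The
#' second peak counts as resolved only if the series dips between the two
#' peak positions (a local minimum below both peak values exists);
#' otherwise the responses overlap and a not-resolvable flag is returned.
#'
#' @param series data.frame from [population_timeseries()] (columns
#'   `time`, `ratio_norm`).
#' @param stim_times the two pulse times on the same time axis.
#' @param window peak search window after each pulse (s, default 15).
#' @param noise_floor minimum first-pulse amplitude for a responding well.
#' @return list with `ratio`, `resolvable`, `amp1`, `amp2`.
#' @export
second_peak_ratio <- function(series, stim_times, window = 15,
                              noise_floor = 0.005) {
  stopifnot(length(stim_times) == 2)
  s <- series$ratio_norm - 1
  t <- series$time
  in1 <- t >= stim_times[1] & t <= stim_times[1] + window
  in2 <- t >= stim_times[2] & t <= stim_times[2] + window
  if (!any(in1) || !any(in2)) stop("peak windows contain no frames")
  i1 <- which(in1)[which.max(s[in1])]
  i2 <- which(in2)[which.max(s[in2])]
  amp1 <- s[i1]; amp2 <- s[i2]
  if (amp1 <= noise_floor)
    stop("non-responding well: first-pulse amplitude at or below noise floor")
  between <- if (i2 > i1 + 1) s[(i1 + 1):(i2 - 1)] else numeric(0)
  resolvable <- length(between) > 0 && min(between) < min(amp1, amp2)
  list(ratio = if (resolvable) amp2 / amp1 else NA_real_,
       resolvable = resolvable, amp1 = amp1, amp2 = amp2)
}
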