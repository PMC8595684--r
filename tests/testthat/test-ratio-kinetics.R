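test_that("ratio images are exact quotients with QC reason codes", {
  fs <- c(32, 32)
  don <- matrix(5000, fs[1], fs[2])
  acc <- 1.2 * don
  mask <- matrix(TRUE, fs[1], fs[2])
  rf <- compute_ratio_image(don, acc, mask, smooth_sigma = 0)
  expect_true(all(abs(rf$ratio - 1.2) < 1e-12))

  # low-ratio pixel invalidated with its reason
  acc2 <- acc; acc2[5, 5] <- 0.7 * don[5, 5]
  rf2 <- compute_ratio_image(don, acc2, mask, smooth_sigma = 0)
  expect_true(is.na(rf2$ratio[5, 5]))
  expect_equal(rf2$reason[5, 5], optofret:::RATIO_REASONS[["low_ratio"]])

  # saturated pixel invalid; zero donor becomes dim, never infinite
  don3 <- don; don3[2, 2] <- 0; acc3 <- acc; acc3[9, 9] <- 65535
  rf3 <- compute_ratio_image(don3, acc3, mask, smooth_sigma = 0)
  expect_equal(rf3$reason[2, 2], optofret:::RATIO_REASONS[["dim"]])
  expect_equal(rf3$reason[9, 9], optofret:::RATIO_REASONS[["saturated"]])
  expect_true(all(is.finite(rf3$ratio[rf3$reason == 0])))

  # saturation invalidation is local: neighbors beyond the smoothing
  # support keep valid finite ratios
  rf4 <- compute_ratio_image(don, acc3, mask, smooth_sigma = 1)
  expect_true(is.na(rf4$ratio[9, 9]))
  expect_false(is.na(rf4$ratio[9, 14]))
})

test_that("population series use ratio of means and normalize the pre-stimulus window to 1", {
  fs <- c(48, 48)
  sp <- scene_params(field_shape = fs, n_frames = 16, n_cells = 3,
                     cell_radius = 2, speed = 0,
                     programmed_amplitude = 0.10,
                     stimuli = list(stimulus_event(9, "global")))
  sc <- make_scene(sp, 21)
  st <- render_frames(sc, identity_optics(fs), noise = FALSE)
  ser <- population_timeseries(st)
  pre <- ser$time <= 0
  expect_equal(mean(ser$ratio_norm[pre]), 1, tolerance = 1e-12)
  expect_equal(min(ser$time[ser$time > 0]), 1.5)

  # ratio-of-means oracle on a heterogeneous frame
  don <- st$donor[[1]]; acc <- st$acceptor[[1]]
  rf <- compute_ratio_image(don, acc, smooth_sigma = 1)
  ok <- rf$reason == 0
  expect_equal(ser$ratio[1], mean(acc[ok]) / mean(don[ok]),
               tolerance = 1e-10)
})

test_that("a programmed ratio step is recovered in the population series", {
  fs <- c(64, 64)
  sp <- scene_params(field_shape = fs, n_frames = 14, n_cells = 4,
                     cell_radius = 2.5, speed = 0,
                     programmed_amplitude = 0.10,
                     stimuli = list(stimulus_event(7.5, "global")))
  sc <- make_scene(sp, 22)
  st <- render_frames(sc, optics_model(fs, vignette_strength = 0,
                                       half_chip_factor = 1, dust = NULL,
                                       bg_level = 0, dark_offset = 0),
                      noise = TRUE)
  ser <- population_timeseries(st)
  inP <- ser$time >= 4.5 & ser$time <= 10.5
  expect_lt(abs(mean(ser$ratio_norm[inP]) - 1 - 0.10), 0.005)
})

test_that("dead cells are excluded by the pixel filters without biasing the series", {
  fs <- c(80, 80)
  base <- scene_params(field_shape = fs, n_frames = 8, n_cells = 6,
                       cell_radius = 2.5, speed = 0,
                       stimuli = list(stimulus_event(6, "global")))
  dead <- base; dead$dead_fraction <- 0.34
  s_base <- population_timeseries(render_frames(make_scene(base, 30),
                                                identity_optics(fs),
                                                noise = FALSE))
  s_dead <- population_timeseries(render_frames(make_scene(dead, 30),
                                                identity_optics(fs),
                                                noise = FALSE))
  expect_lt(max(abs(s_dead$ratio_norm - s_base$ratio_norm)), 0.005)
})

test_that("single-cell fold changes report P/C2 and C1/C2 with the dead-cell and window screens", {
  times <- seq(0, 37.5, by = 1.5)
  stim_time <- 15.75  # last pre-stimulus frame at 15 s
  fs <- c(40, 40)
  lab <- matrix(0L, fs[1], fs[2]); lab[10:20, 10:20] <- 1L
  labels <- rep(list(lab), length(times))
  mk_frames <- function(level_fun) lapply(seq_along(times), function(fr) {
    r <- matrix(NA_real_, fs[1], fs[2])
    r[lab == 1L] <- level_fun(times[fr] - 15)
    structure(list(ratio = r, reason = (lab == 0L) * 1L),
              class = "fret_ratio_frame")
  })
  tracks <- data.frame(track = 1, frame = seq_along(times), label = 1L,
                       cx = 14, cy = 14, cx_um = 4.5, cy_um = 4.5,
                       area = 121L, complete = TRUE)
  # flat cell: both fold changes exactly 1
  fc <- single_cell_fold_change(tracks, mk_frames(function(t) 1.05),
                                labels, times, stim_time)
  expect_equal(fc$p_c2, 1)
  expect_equal(fc$c1_c2, 1)
  expect_true(fc$included)

  # +8% response confined to the peak window
  fc2 <- single_cell_fold_change(
    tracks, mk_frames(function(t) if (t >= 4.5 && t <= 10.5) 1.08 else 1.0),
    labels, times, stim_time)
  expect_equal(fc2$p_c2, 1.08, tolerance = 1e-12)
  expect_equal(fc2$c1_c2, 1)

  # baseline 0.90: excluded by the dead-cell rule
  fc3 <- single_cell_fold_change(tracks, mk_frames(function(t) 0.90),
                                 labels, times, stim_time)
  expect_false(fc3$included)
  expect_equal(fc3$reason, "low_baseline")

  # incomplete track excluded with its reason
  tr_inc <- tracks[1:10, ]; tr_inc$complete <- FALSE
  fc4 <- single_cell_fold_change(tr_inc, mk_frames(function(t) 1.05),
                                 labels, times, stim_time)
  expect_equal(fc4$reason, "incomplete_track")
})

test_that("response histograms average relative frequencies across experiments", {
  h1 <- response_histograms(list(a = rep(1.0, 10)),
                            breaks = seq(0.9, 1.4, length.out = 6))
  expect_equal(sum(h1$mean), 1)
  expect_equal(max(h1$mean), 1)  # all mass in one bin

  # identical groups: SEM identically zero
  h2 <- response_histograms(list(a = c(1, 1.1, 1.2), b = c(1, 1.1, 1.2)))
  expect_true(all(h2$sem == 0))

  # bimodal mixture: modes at 1.0 and the programmed amplitude
  set.seed(31)
  g <- replicate(3, c(rnorm(300, 1.0, 0.01), rnorm(300, 1.10, 0.01)),
                 simplify = FALSE)
  h3 <- response_histograms(setNames(g, paste0("e", 1:3)))
  top2 <- h3$mid[order(h3$mean, decreasing = TRUE)[1:2]]
  expect_lt(min(abs(sort(top2) - c(1.0, 1.10))), 0.0125)
  expect_warning(response_histograms(list(a = 1, b = numeric(0))),
                 "empty")
})

test_that("second-peak amplitude ratios handle symmetric, halved, and unresolvable cases", {
  t <- seq(-6, 60, by = 1.5)
  pulse <- function(t0, amp) ifelse(t >= t0, amp * (t - t0) / 4 *
                                      exp(1 - (t - t0) / 4), 0)
  mk <- function(a2, dt) data.frame(time = t,
                                    ratio_norm = 1 + pulse(0, 0.1) +
                                      pulse(dt, a2))
  r1 <- second_peak_ratio(mk(0.1, 28), c(0, 28))
  expect_true(r1$resolvable)
  expect_equal(r1$ratio, 1, tolerance = 0.05)

  r2 <- second_peak_ratio(mk(0.05, 28), c(0, 28))
  expect_equal(r2$ratio, 0.5, tolerance = 0.1)

  # 7 s delay: responses overlap into one rise, no dip between peaks
  r3 <- second_peak_ratio(mk(0.1, 7), c(0, 7), window = 15)
  expect_false(r3$resolvable)
  expect_true(is.na(r3$ratio))

  flat <- data.frame(time = t, ratio_norm = rep(1, length(t)))
  expect_error(second_peak_ratio(flat, c(0, 28)), "non-responding")
})
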