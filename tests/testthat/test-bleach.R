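# helper: uniform-field pre/post bleach intensity images
bleach_pair <- function(fs, pixel_size, b0, sigma0, center, level = 4000,
                        noise = FALSE, seed = 1) {
  x <- matrix(rep(0:(fs[2] - 1), each = fs[1]), fs[1], fs[2])
  y <- matrix(rep(0:(fs[1] - 1), times = fs[2]), fs[1], fs[2])
  r2 <- ((x - center[1]) * pixel_size)^2 + ((y - center[2]) * pixel_size)^2
  post <- level * (1 - b0 * exp(-r2 / (2 * sigma0^2)))
  pre <- matrix(level, fs[1], fs[2])
  if (noise) {
    set.seed(seed)
    post <- matrix(rpois(length(post), post), fs[1], fs[2])
    pre <- matrix(rpois(length(pre), pre), fs[1], fs[2])
  }
  list(pre = pre, post = post)
}

test_that("the initial bleach profile fit inverts the forward model", {
  fs <- c(64, 64); px <- 0.325; ctr <- c(32, 32)
  p <- bleach_pair(fs, px, b0 = 0.3, sigma0 = 1.5, ctr)
  fit <- fit_bleach_profile(p$post, p$pre, ctr, px)
  expect_equal(fit$b0, 0.3, tolerance = 0.01)
  expect_equal(fit$sigma0, 1.5, tolerance = 0.01)

  # identical pre/post: no bleach
  fit0 <- fit_bleach_profile(p$pre, p$pre, ctr, px)
  expect_equal(fit0$b0, 0)
})

test_that("free diffusion conserves the bleached amount and matches a finite-difference oracle", {
  bm <- bleach_model(b0 = 0.3, sigma0 = 1.5, D = 0.5, center = c(80, 80))
  fs <- c(161, 161); px <- 0.25
  b0 <- propagate_bleach(bm, 0, fs, px)
  b10 <- propagate_bleach(bm, 10, fs, px)
  expect_equal(max(b0), 0.3, tolerance = 1e-9)       # initial condition
  expect_lt(max(b10), max(b0))                        # monotone spreading
  expect_equal(sum(b10) / sum(b0), 1, tolerance = 1e-3)  # conservation

  # explicit finite-difference diffusion oracle on a fine grid (domain
  # wide enough that the zero-flux boundary is ~5 sigma out)
  h <- 0.1; n <- 201
  xs <- (seq_len(n) - (n + 1) / 2) * h
  f <- outer(xs, xs, function(a, b2) 0.3 * exp(-(a^2 + b2^2) / (2 * 1.5^2)))
  dt <- 1e-3; D <- 0.5
  for (step in seq_len(2000)) {
    lap <- (rbind(f[-1, ], f[n, ]) + rbind(f[1, ], f[-n, ]) +
              cbind(f[, -1], f[, n]) + cbind(f[, 1], f[, -n]) - 4 * f) / h^2
    f <- f + dt * D * lap
  }
  bm2 <- bleach_model(b0 = 0.3, sigma0 = 1.5, D = 0.5,
                      center = c((n - 1) / 2, (n - 1) / 2))
  closed <- propagate_bleach(bm2, 2, c(n, n), h)
  expect_lt(max(abs(closed - f)) / max(f), 0.005)
})

test_that("amplitudes scale linearly with stimulus power relative to calibration", {
  bm <- bleach_model(b0 = 0.37, sigma0 = 1.5, D = 0.5,
                     calibration_power = 37, center = c(20, 20))
  b <- propagate_bleach(bm, 0, c(41, 41), 0.325, power = 0.8)
  expect_equal(max(b), 0.37 * 0.8 / 37, tolerance = 1e-12)
})

test_that("recovery-series fitting returns the generating diffusion coefficient", {
  fs <- c(64, 64); px <- 0.325; ctr <- c(32, 32)
  times <- seq(0.5, 10, by = 0.5)
  bm <- bleach_model(b0 = 0.3, sigma0 = 1.5, D = 0.5, center = ctr)
  set.seed(41)
  pre <- matrix(rpois(prod(fs), 4000), fs[1], fs[2])
  frames <- lapply(times, function(t) {
    b <- propagate_bleach(bm, t, fs, px)
    matrix(rpois(prod(fs), 4000 * (1 - b)), fs[1], fs[2])
  })
  fit <- fit_bleach_series(frames, times, pre, ctr, px)
  expect_equal(fit$D, 0.5, tolerance = 0.1)
  expect_equal(fit$b0, 0.3, tolerance = 0.1)
})

test_that("ratio correction for the bleached pool is exact where the bias model holds", {
  fs <- c(64, 64); px <- 0.325
  stim <- stimulus_event(2, "focal", power = 37, target = c(32, 32))
  bm <- bleach_model(b0 = 0.3, sigma0 = 2.0, D = 0.5, alpha = 1,
                     calibration_power = 37)
  times <- c(0, 2.5, 5)
  truth <- matrix(1.1, fs[1], fs[2])
  frames <- lapply(times, function(t) {
    if (t < stim$time) return(truth)
    b <- propagate_bleach(bm, t - stim$time, fs, px, center = stim$target)
    truth * (1 - bm$alpha * b)
  })
  corr <- correct_ratio_series(frames, bm, list(stim), times, px)
  for (k in 2:3)
    expect_equal(corr[[k]], truth, tolerance = 1e-12)
  # zero-power stimulus: identity
  stim0 <- stimulus_event(2, "focal", power = 0, target = c(32, 32))
  corr0 <- correct_ratio_series(list(truth), bm, list(stim0), 5, px)
  expect_equal(corr0[[1]], truth)
  # alpha = 0: identity even with b > 0
  bm0 <- bleach_model(b0 = 0.3, sigma0 = 2, D = 0.5, alpha = 0)
  corrA <- correct_ratio_series(list(truth), bm0, list(stim), 5, px)
  expect_equal(corrA[[1]], truth)
  # correction locality: beyond 5 sigma the factor is essentially 1
  b5 <- propagate_bleach(bm, 3, fs, px, center = c(32, 32))
  s_t <- sqrt(2^2 + 2 * 0.5 * 3)
  x <- matrix(rep(0:(fs[2] - 1), each = fs[1]), fs[1], fs[2])
  y <- matrix(rep(0:(fs[1] - 1), times = fs[2]), fs[1], fs[2])
  rr <- sqrt(((x - 32) * px)^2 + ((y - 32) * px)^2)
  expect_lt(max(b5[rr > 5 * s_t]), 1e-6)
})

test_that("round trip: rendered bleach scenes are corrected to the true ratio", {
  fs <- c(72, 72); px <- 0.325
  stim <- stimulus_event(2, "focal", power = 37, target = c(36, 36))
  sp <- scene_params(field_shape = fs, n_frames = 6, n_cells = 1,
                     cell_radius = 7, speed = 0, sensor_density = 20000,
                     frame_interval = 1.5, stimuli = list(stim))
  sc <- make_scene(sp, 17)
  bm <- bleach_model(b0 = 0.3, sigma0 = 1.5, D = 0.5, alpha = 0.8,
                     calibration_power = 37)
  x <- matrix(rep(0:(fs[2] - 1), each = fs[1]), fs[1], fs[2])
  y <- matrix(rep(0:(fs[1] - 1), times = fs[2]), fs[1], fs[2])
  rr <- sqrt(((x - 36) * px)^2 + ((y - 36) * px)^2)

  # model fidelity: noiseless render corrected exactly (pixelwise)
  stn <- render_bleach(sc, identity_optics(fs), bm, noise = FALSE)
  rfn <- ratio_frames(stn, smooth_sigma = 0)
  cn <- correct_ratio_series(rfn, bm, list(stim), stn$times, px)
  for (fr in c(3, 5)) {
    tr <- scene_true_ratio(sc, fr)
    got <- cn[[fr]]$ratio
    ok <- !is.na(tr) & !is.na(got) & rr >= 0.5
    expect_gt(sum(ok), 500)
    expect_lt(max(abs(got[ok] / tr[ok] - 1)), 0.01)
  }

  # with shot noise, radial-bin means stay within 1% of truth
  st <- render_bleach(sc, identity_optics(fs), bm, noise = TRUE)
  rframes <- ratio_frames(st, smooth_sigma = 0)
  corr <- correct_ratio_series(rframes, bm, list(stim), st$times, px)
  for (fr in c(3, 5)) {
    tr <- scene_true_ratio(sc, fr)
    got <- corr[[fr]]$ratio
    ok <- !is.na(tr) & !is.na(got) & rr >= 0.5
    bins <- floor(rr[ok])
    rel <- tapply(got[ok] / tr[ok], bins, mean)
    n <- tapply(bins, bins, length)
    expect_lt(max(abs(rel[n >= 20] - 1)), 0.01)
  }
})
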