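test_that("dark correction is the per-pixel median and subtracts exactly", {
  frames <- lapply(1:79, function(i) matrix(100, 8, 8))
  expect_equal(build_dark_correction(frames), matrix(100, 8, 8))

  # known per-pixel median against a direct sort oracle
  set.seed(1)
  frames <- lapply(1:9, function(i) matrix(sample(90:110, 16, TRUE), 4, 4))
  dark <- build_dark_correction(frames)
  arr <- array(unlist(frames), c(4, 4, 9))
  for (k in sample(16, 4)) {
    rc <- arrayInd(k, c(4, 4))
    expect_equal(dark[rc], sort(arr[rc[1], rc[2], ])[5])
  }
  expect_error(build_dark_correction(frames[1]), "at least 2")

  cs <- correction_set(dark, dark)
  expect_equal(apply_corrections(dark, "donor", cs), matrix(0, 4, 4))
})

test_that("half-chip factor is the above/below row-mean ratio on a step image", {
  img <- matrix(100, 16, 10)
  hc <- build_half_chip_correction(img)
  expect_equal(hc$factor, 1)
  expect_equal(hc$field, matrix(1, 16, 10))

  img[9:16, ] <- 50  # bottom half dimmer
  hc <- build_half_chip_correction(img)
  expect_equal(hc$factor, 2)
  expect_equal(hc$field[1:8, 1], rep(1, 8))
  expect_equal(hc$field[9:16, 1], rep(2, 8))
  expect_error(build_half_chip_correction(matrix(0, 16, 4)), "zero mean")

  # 3% step plus noise recovers the noiseless factor within 0.3%
  set.seed(2)
  base <- matrix(1000, 64, 64)
  base[33:64, ] <- 970
  noisy <- base + matrix(rnorm(64 * 64, 0, 5), 64, 64)
  hc <- build_half_chip_correction(noisy)
  expect_equal(hc$factor, 1 / 0.97, tolerance = 0.003)
})

test_that("dust correction restores a dim spot and leaves clean chips untouched", {
  expect_equal(build_dust_correction(matrix(1000, 64, 64)),
               matrix(1, 64, 64))

  fs <- c(96, 96)
  x <- matrix(rep(0:(fs[2] - 1), each = fs[1]), fs[1], fs[2])
  y <- matrix(rep(0:(fs[1] - 1), times = fs[2]), fs[1], fs[2])
  dye <- 2000 * (1 - 0.2 * exp(-((x - 40)^2 + (y - 56)^2) / (2 * 8^2)))
  corr <- build_dust_correction(dye)
  fixed <- dye * corr
  expect_lt(abs(fixed[57, 41] - 2000) / 2000, 0.01)  # spot center restored
  expect_equal(corr[5, 5], 1)                        # far field exactly 1

  # a quarter-chip dim area is not dust
  bad <- matrix(1000, 64, 64); bad[1:32, 1:32] <- 700
  expect_error(build_dust_correction(bad), "flagged as dust")
})

test_that("ratio correction removes an imposed gradient and is mean-1 neutral", {
  fs <- c(96, 96)
  grad <- matrix(rep(seq(0.9, 1.1, length.out = fs[1]), fs[2]), fs[1], fs[2])
  set.seed(3)
  imgs <- list(); masks <- list()
  for (i in 1:12) {
    m <- matrix(FALSE, fs[1], fs[2])
    # random cell patches scattered densely over the field (the protocol
    # requires cells on every portion of the sensor)
    for (k in 1:60) {
      r <- sample(5:(fs[1] - 5), 1); c <- sample(5:(fs[2] - 5), 1)
      m[(r - 3):(r + 3), (c - 3):(c + 3)] <- TRUE
    }
    imgs[[i]] <- 1.2 * grad + matrix(rnorm(prod(fs), 0, 0.005), fs[1], fs[2])
    masks[[i]] <- m
  }
  rc <- build_ratio_correction(imgs, masks)
  expect_equal(mean(rc), 1, tolerance = 1e-12)
  corrected <- (1.2 * grad) / rc
  # residual top-to-bottom slope under 1% of the mean level
  rows <- rowMeans(corrected)
  slope <- coef(lm(rows ~ seq_along(rows)))[2] * fs[1]
  expect_lt(abs(slope) / mean(rows), 0.01)

  # constant ratio field: correction is exactly 1 after mean-1 rescale
  flat <- lapply(1:3, function(i) matrix(1.2, 48, 48))
  fm <- lapply(1:3, function(i) matrix(TRUE, 48, 48))
  expect_equal(build_ratio_correction(flat, fm), matrix(1, 48, 48))
  expect_error(build_ratio_correction(list(), list()), "empty mask|no calibration")
})

test_that("multiplicative field application order commutes and identity corrections are a no-op", {
  set.seed(4)
  frame <- matrix(runif(64 * 64, 500, 4000), 64, 64)
  hc <- matrix(rep(c(1, 1.03), each = 32 * 64 / 64), 64, 64)
  dust <- 1 + 0.1 * matrix(runif(64 * 64), 64, 64)
  expect_equal((frame * hc) * dust, (frame * dust) * hc, tolerance = 1e-12)

  cs <- identity_corrections(c(64, 64))
  expect_equal(apply_corrections(frame, "acceptor", cs), frame)
  expect_error(apply_corrections(frame[1:10, ], "donor", cs), "shape")
})

test_that("calibration stacks processed end to end flatten the chip artifacts", {
  fs <- c(128, 128)
  optics <- optics_model(fs, vignette_strength = 0, half_chip_factor = 0.94,
                         dust = list(center = c(40, 80), radius_px = 10,
                                     depth = 0.2),
                         dark_offset = 100, read_noise_sd = 3, gain = 2)
  dark <- list(donor = render_calibration("dark", optics, 25, "donor"),
               acceptor = render_calibration("dark", optics, 25, "acceptor"))
  dye <- list(donor = render_calibration("dye", optics, 79, "donor",
                                         dye_level = 10000),
              acceptor = render_calibration("dye", optics, 79, "acceptor",
                                            dye_level = 10000))
  cs <- build_correction_set(dark, dye)
  arr <- array(unlist(dye$donor), c(fs, 79))
  med <- apply(arr, c(1, 2), median)
  un <- med - cs$dark$donor
  corrected <- apply_corrections(med, "donor", cs)
  cv <- function(m) sd(m) / mean(m)
  expect_gt(cv(un), 0.03)
  expect_lt(cv(corrected), 0.005)
})
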