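test_that("background estimation recovers a constant offset in dense-well mode", {
  fs <- c(64, 64)
  frames <- lapply(1:5, function(i) matrix(1400, fs[1], fs[2]))
  profile <- matrix(700, fs[1], fs[2])  # same shape, different scale
  bg <- estimate_background(frames, "dense", empty_profile = profile)
  expect_lt(max(abs(bg$background - 1400)), 1)
  # with read/shot noise the dim-pixel selection is slightly low-biased;
  # the recovered level stays within a few counts of truth
  set.seed(8)
  noisy <- lapply(1:5, function(i)
    matrix(1400 + rnorm(prod(fs), 0, 3), fs[1], fs[2]))
  bgn <- estimate_background(noisy, "dense", empty_profile = profile)
  expect_lt(max(abs(bgn$background - 1400)), 8)
  # empty frame: essentially every pixel is background at the 1.5 pctile cut
  expect_gt(mean(bg$mask), 0.01)
  expect_error(estimate_background(list(), "dense", profile), "empty")
})

test_that("sparse-mode background reproduces a smooth field under cells", {
  fs <- c(96, 96)
  x <- matrix(rep(0:(fs[2] - 1), each = fs[1]), fs[1], fs[2])
  truth <- 200 + 0.5 * x
  img <- truth
  img[30:50, 30:50] <- img[30:50, 30:50] + 3000  # a bright cell
  bg <- estimate_background(list(img), "sparse", radius = 40)
  err <- abs(bg$background - truth)
  expect_lt(mean(err), 6)
})

test_that("segmentation finds disks, is scale invariant, and enforces area limits", {
  fs <- c(128, 128)
  img <- matrix(0, fs[1], fs[2])
  d1 <- disk_mask(fs, 35, 40, 10)
  d2 <- disk_mask(fs, 90, 80, 10)
  img[d1] <- 1000; img[d2] <- 1000
  set.seed(9)
  noisy <- img + matrix(rnorm(prod(fs), 0, 100), fs[1], fs[2])
  lab <- segment_cells(noisy, min_area = 80, max_area = 2000)
  objs <- attr(lab, "objects")
  expect_equal(nrow(objs), 2)
  iou <- function(a, b) sum(a & b) / sum(a | b)
  got1 <- lab == lab[41, 36]
  expect_gt(iou(got1, d1), 0.9)

  # intensity-scale invariance: masks identical under positive rescaling
  expect_equal(unname(segment_cells(noisy * 7.3) > 0),
               unname(segment_cells(noisy) > 0))

  # pure noise: no objects after area filtering
  pure <- matrix(rnorm(prod(fs), 0, 50), fs[1], fs[2])
  expect_equal(nrow(attr(segment_cells(pure), "objects")), 0)

  # a disk below the minimum area is dropped
  small <- matrix(0, 64, 64); small[disk_mask(c(64, 64), 30, 30, 3)] <- 1000
  expect_equal(max(segment_cells(small, min_area = 80)), 0)
  big <- segment_cells(small, min_area = 5, max_area = 2000)
  expect_equal(max(big), 1)
})

test_that("reciprocal nearest-neighbor tracking matches a brute-force oracle", {
  oracle_links <- function(a, b, max_dist = Inf) {
    res <- list()
    for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
      dij <- sqrt(sum((a[i, ] - b[j, ])^2))
      if (dij > max_dist) next
      di <- sqrt(rowSums((b - matrix(unlist(a[i, ]), nrow(b), 2,
                                     byrow = TRUE))^2))
      dj <- sqrt(rowSums((a - matrix(unlist(b[j, ]), nrow(a), 2,
                                     byrow = TRUE))^2))
      if (sum(di == min(di)) == 1 && which.min(di) == j &&
          sum(dj == min(dj)) == 1 && which.min(dj) == i)
        res[[length(res) + 1]] <- c(i, j)
    }
    if (!length(res)) return(matrix(numeric(0), 0, 2))
    do.call(rbind, res)
  }
  set.seed(10)
  for (rep in 1:10) {
    a <- data.frame(cx = runif(8, 0, 50), cy = runif(8, 0, 50))
    b <- data.frame(cx = runif(7, 0, 50), cy = runif(7, 0, 50))
    got <- reciprocal_nn_links(a, b, max_dist = 20)
    want <- oracle_links(a, b, max_dist = 20)
    expect_equal(nrow(got), nrow(want))
    if (nrow(got)) expect_equal(as.matrix(got[, 1:2]),
                                want, ignore_attr = TRUE)
  }
})

test_that("exact distance ties break reciprocity (no link)", {
  a <- data.frame(cx = c(0, 10), cy = c(0, 0))
  b <- data.frame(cx = 5, cy = 0)  # equidistant from both
  expect_equal(nrow(reciprocal_nn_links(a, b)), 0)
})

test_that("drifting cells are tracked with fully correct identities", {
  set.seed(12)
  n <- 20; nT <- 20
  pos0 <- cbind(runif(n, 10, 190), runif(n, 10, 190))
  # spacing-aware drift: steps well below half the minimum spacing
  objs <- list()
  pos <- pos0
  truth <- list()
  for (t in 1:nT) {
    objs[[t]] <- data.frame(label = 1:n, cx = pos[, 1], cy = pos[, 2],
                            area = 100L)
    truth[[t]] <- 1:n
    pos <- pos + matrix(runif(2 * n, -1.5, 1.5), n, 2)
  }
  tracks <- track_cells(objs, pixel_size = 1, max_link = 10)
  expect_equal(length(unique(tracks$track)), n)
  expect_true(all(tracks$complete))
  # identity: each track keeps one label throughout
  for (tr in unique(tracks$track)) {
    labs <- tracks$label[tracks$track == tr]
    expect_equal(length(unique(labs)), 1)
  }
})

test_that("stationary objects produce complete zero-displacement tracks", {
  objs <- lapply(1:5, function(t)
    data.frame(label = 1:3, cx = c(5, 25, 45), cy = c(5, 25, 45),
               area = 50L))
  tracks <- track_cells(objs, pixel_size = 0.5)
  expect_true(all(tracks$complete))
  disp <- tapply(tracks$cx, tracks$track, function(v) diff(range(v)))
  expect_true(all(disp == 0))
})
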