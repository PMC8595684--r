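test_that("protrusion detection keeps the largest new-edge region with temporal consistency", {
  fs <- c(60, 60)
  d0 <- disk_mask(fs, 25, 30, 10)
  d1 <- disk_mask(fs, 27, 30, 10)
  d2 <- disk_mask(fs, 29, 30, 10)
  # stationary mask: empty protrusion
  expect_false(any(detect_protrusion(d0, d0, require_neighbors = FALSE)))

  # crescent area matches the analytic lens complement of two offset disks
  p01 <- detect_protrusion(d0, d1, require_neighbors = FALSE)
  r <- 10; d <- 2
  lens <- 2 * r^2 * acos(d / (2 * r)) - d / 2 * sqrt(4 * r^2 - d^2)
  expect_equal(sum(p01), pi * r^2 - lens, tolerance = 0.1 * sum(p01))

  # consistent motion: middle protrusion confirmed by its neighbors
  p12 <- detect_protrusion(d1, d2, require_neighbors = FALSE)
  mid <- detect_protrusion(d0, d1, prev_protrusion = p01,
                           next_protrusion = p12)
  expect_true(any(mid))

  # a transient blob absent in neighboring frames is rejected
  blob <- d1; blob[5:8, 5:8] <- TRUE
  pt <- detect_protrusion(d1, blob, prev_protrusion = p01,
                          next_protrusion = p12)
  expect_false(any(pt))

  # first/last frames have no neighbor: no protrusion defined
  expect_false(any(detect_protrusion(d0, d1, NULL, p12)))
})

test_that("geodesic distance matches Dijkstra on random masks and closed forms", {
  # source pixel itself is zero; a 1-px corridor is a chain graph
  corridor <- matrix(FALSE, 5, 12); corridor[3, 2:11] <- TRUE
  src <- matrix(FALSE, 5, 12); src[3, 2] <- TRUE
  g <- geodesic_distance(corridor, src, pixel_size = 0.5)
  expect_equal(g[3, 2], 0)
  expect_equal(g[3, 11], 9 * 0.5)

  # convex mask: geodesic equals quasi-Euclidean chamfer >= Euclidean
  fs <- c(41, 41)
  dm <- disk_mask(fs, 20, 20, 15)
  srcm <- matrix(FALSE, fs[1], fs[2]); srcm[21, 21] <- TRUE
  gd <- geodesic_distance(dm, srcm)
  x <- matrix(rep(0:40, each = 41), 41, 41); y <- t(x)
  eu <- sqrt((x - 20)^2 + (y - 20)^2)
  expect_true(all(gd[dm] >= eu[dm] - 1e-9))
  expect_lt(max(gd[dm] - eu[dm]) / max(eu[dm]), 0.09)  # chamfer overshoot

  skip_if_not_installed("igraph")
  dijkstra_oracle <- function(mask, source) {
    idx <- which(mask)
    id <- match(seq_len(length(mask)), idx)
    nr <- nrow(mask)
    edges <- c(); w <- c()
    rc <- arrayInd(idx, dim(mask))
    for (k in seq_along(idx)) {
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0 && dc == 0) next
        r2 <- rc[k, 1] + dr; c2 <- rc[k, 2] + dc
        if (r2 < 1 || r2 > nrow(mask) || c2 < 1 || c2 > ncol(mask)) next
        if (!mask[r2, c2]) next
        j <- id[(c2 - 1) * nr + r2]
        edges <- c(edges, k, j)
        w <- c(w, if (dr != 0 && dc != 0) sqrt(2) else 1)
      }
    }
    g <- igraph::make_graph(edges, n = length(idx), directed = FALSE)
    srcs <- which(idx %in% which(source))
    d <- igraph::distances(g, v = srcs, weights = rep(w, 1))
    out <- matrix(NA_real_, nrow(mask), ncol(mask))
    out[idx] <- apply(d, 2, min)
    out
  }
  set.seed(13)
  for (rep in 1:20) {
    mask <- matrix(runif(30 * 30) < 0.65, 30, 30)
    if (!any(mask)) next
    pts <- which(mask)
    source <- matrix(FALSE, 30, 30)
    source[sample(pts, min(2, length(pts)))] <- TRUE
    got <- geodesic_distance(mask, source)
    want <- dijkstra_oracle(mask, source)
    expect_equal(got[mask], want[mask], tolerance = 1e-12)
  }
  expect_error(geodesic_distance(mask, matrix(FALSE, 30, 30)), "empty source")
})

test_that("edge-distance profiles are 1 at the leading edge and track gradients", {
  fs <- c(50, 50); px <- 0.5
  mask <- disk_mask(fs, 25, 25, 15)
  prot <- matrix(FALSE, fs[1], fs[2])
  prot[, 41:44] <- mask[, 41:44]; mask2 <- mask & !prot
  # uniform ratio: profile identically 1 after normalization
  uni <- matrix(1.1, fs[1], fs[2]); uni[!mask] <- NA
  pr <- edge_distance_profile(list(uni), list(mask2), list(prot), px)
  expect_equal(pr$mean_ratio[1], 1)
  expect_true(all(abs(pr$mean_ratio - 1) < 1e-12))

  # front-high linear gradient decays along distance from the protrusion
  x <- matrix(rep(0:(fs[2] - 1), each = fs[1]), fs[1], fs[2])
  gradient <- 1.2 - 0.01 * (42 - x)  # high at the protrusion side
  gradient[!mask] <- NA
  pg <- edge_distance_profile(list(gradient), list(mask2), list(prot), px)
  expect_true(all(diff(pg$mean_ratio[1:10]) < 0))
  slope <- coef(lm(pg$mean_ratio ~ pg$distance))[2]
  expect_equal(unname(slope), -0.01 / px / 1.2, tolerance = 0.15)
})

test_that("center-stimulation screening rejects motion, edge proximity, and off-cell targets", {
  fs <- c(60, 60); px <- 0.5
  masks <- rep(list(disk_mask(fs, 30, 30, 14)), 6)
  track <- data.frame(frame = 1:6, cx_um = 15, cy_um = 15)
  keep <- screen_center_stim_cell(track, masks, c(30, 30), 2, px)
  expect_true(keep$keep)

  # stimulus pixel outside the mask
  off <- screen_center_stim_cell(track, masks, c(2, 2), 2, px)
  expect_equal(off$reason, "stimulus_outside_mask")

  # three pixels from the edge
  near <- screen_center_stim_cell(track, masks, c(30 + 12, 30), 2, px)
  expect_equal(near$reason, "stimulus_near_edge")

  # centroid drifting 5 um post stimulus
  drift <- track; drift$cx_um <- c(15, 15, 16, 18, 20, 20)
  mv <- screen_center_stim_cell(drift, masks, c(30, 30), 2, px)
  expect_equal(mv$reason, "excess_motion")
})

test_that("radial profiles bin annuli exactly and fold changes reference the pre-stimulus frame", {
  fs <- c(80, 80); px <- 0.325
  mask <- disk_mask(fs, 40, 40, 30)
  don <- matrix(1000, fs[1], fs[2])
  acc_pre <- 1.0 * don
  acc_post <- 1.08 * don  # uniform +8% response
  prof <- radial_profile(list(don, don), list(acc_pre, acc_post),
                         list(mask, mask), c(40, 40), pre_frame = 1, px)
  post <- prof[prof$frame == 2 & !is.na(prof$fold_change), ]
  expect_true(all(abs(post$fold_change - 1.08) < 1e-12))
  pre <- prof[prof$frame == 1 & !is.na(prof$fold_change), ]
  expect_true(all(abs(pre$fold_change - 1) < 1e-12))
  # bins partition the mask: per-frame pixel counts reconcile
  expect_equal(sum(prof$n_px[prof$frame == 1]), sum(mask))

  # Gaussian response: bin fold changes match analytic annulus averages
  x <- matrix(rep(0:(fs[2] - 1), each = fs[1]), fs[1], fs[2])
  y <- matrix(rep(0:(fs[1] - 1), times = fs[2]), fs[1], fs[2])
  r2um <- (((x - 40) * px)^2 + ((y - 40) * px)^2)
  acc_g <- don * (1 + 0.1 * exp(-r2um / (2 * 2^2)))
  pg <- radial_profile(list(don, don), list(acc_pre, acc_g),
                       list(mask, mask), c(40, 40), pre_frame = 1, px)
  pg2 <- pg[pg$frame == 2 & pg$bin <= 8, ]
  for (k in seq_len(nrow(pg2))) {
    b <- pg2$bin[k]
    rs <- seq((b - 1), b, length.out = 200)
    analytic <- 1 + 0.1 * sum(rs * exp(-rs^2 / 8)) / sum(rs)
    expect_equal(pg2$fold_change[k], analytic, tolerance = 0.05)
  }
})

test_that("edge-target selection agrees with a brute-force perimeter search", {
  fs <- c(61, 61)
  mask <- disk_mask(fs, 30, 30, 20)
  expect_equal(select_edge_target(mask, target_angle = 0)[1], 50)  # rightmost
  top <- select_edge_target(mask, target_angle = 90)
  expect_equal(top[2], 10)  # topmost row (y up convention)

  # irregular mask, many angles, vs exhaustive search over perimeter pixels
  set.seed(14)
  blob <- disk_mask(fs, 28, 32, 14) | disk_mask(fs, 38, 22, 9)
  interior <- optofret:::.erode1(blob)
  per <- which(blob & !interior, arr.ind = TRUE)
  cx <- mean(which(blob, arr.ind = TRUE)[, 2] - 1)
  cy <- mean(which(blob, arr.ind = TRUE)[, 1] - 1)
  for (ang in runif(25, -180, 180)) {
    got <- select_edge_target(blob, target_angle = ang)
    px_ <- per[, 2] - 1; py_ <- per[, 1] - 1
    a <- atan2(-(py_ - cy), px_ - cx) * 180 / pi
    diff <- abs(((a - ang + 180) %% 360) - 180)
    best <- which(diff == min(diff))
    if (length(best) > 1) {
      dist <- sqrt((px_ - cx)^2 + (py_ - cy)^2)
      best <- best[which.max(dist[best])]
    }
    expect_equal(got, c(px_[best], py_[best]))
  }
  expect_error(select_edge_target(matrix(FALSE, 3, 3)), "empty mask")
})
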