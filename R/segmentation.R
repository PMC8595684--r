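# Cell segmentation and frame-to-frame tracking.
#
# Cells are detected on summed donor+acceptor images (better
# signal-to-noise, insensitive to FRET redistribution): background
# subtraction, Gaussian smoothing, unsharp masking, Otsu threshold,
# 8-connected components, area filtering. Tracking links objects across
# frames only when two objects are mutually each other's nearest
# neighbors within a distance gate.

#' Estimate the image background
#'
#' Two modes. Dense-well mode ("dense"): the dimmest pixels (default 1.5
#' percentile of the per-pixel median across frames) define background; a
#' supplied empty-well profile is scaled to match them and used as the
#' background image. Sparse/TIRF mode ("sparse"): conservative background
#' pixels (below the Otsu threshold of the median image) feed a
#' local-neighborhood median background image.
#'
#' @param sum_stack list of summed-channel frames.
#' @param mode "dense" or "sparse".
#' @param empty_profile empty-well profile image (dense mode).
#' @param percentile background percentile (fraction, default 0.015).
#' @param radius neighborhood radius in pixels for sparse mode (default
#'   65, much larger than a cell diameter).
#' @param grid_step coarse evaluation step for the local median (px).
#' @return list with `background` (matrix), `mask` (logical background
#'   pixels), `scale` (dense mode).
#' @export
estimate_background <- function(sum_stack, mode = c("dense", "sparse"),
                                empty_profile = NULL, percentile = 0.015,
                                radius = 65, grid_step = 8) {
  mode <- match.arg(mode)
  if (length(sum_stack) == 0) stop("empty stack")
  d <- dim(sum_stack[[1]])
  a <- array(unlist(sum_stack), c(d, length(sum_stack)))
  med <- apply(a, c(1, 2), stats::median)
  if (mode == "dense") {
    if (is.null(empty_profile))
      stop("dense-well mode requires an empty-well profile image")
    thr <- finite_quantile(med, percentile)
    bg_mask <- med <= thr
    if (!any(bg_mask))
      stop("no background pixels found: dense-well mode misuse on a saturated field")
    scale <- stats::median(med[bg_mask]) /
      stats::median(empty_profile[bg_mask])
    list(background = empty_profile * scale, mask = bg_mask, scale = scale)
  } else {
    thr <- otsu_threshold(med)
    bg_mask <- med < thr
    if (!any(bg_mask)) bg_mask <- med <= finite_quantile(med, percentile)
    bg <- .local_median_background(med, bg_mask, radius, grid_step)
    list(background = bg, mask = bg_mask, scale = NA_real_)
  }
}

# Local median of background pixels within `radius`, evaluated on a
# coarse grid and interpolated (cells are small relative to radius).
.local_median_background <- function(img, bg_mask, radius, grid_step) {
  d <- dim(img)
  ry <- unique(c(seq(1, d[1], by = grid_step), d[1]))
  rx <- unique(c(seq(1, d[2], by = grid_step), d[2]))
  coarse <- matrix(NA_real_, length(ry), length(rx))
  idx <- which(bg_mask, arr.ind = TRUE)
  for (i in seq_along(ry)) {
    dy2 <- (idx[, 1] - ry[i])^2
    for (j in seq_along(rx)) {
      sel <- dy2 + (idx[, 2] - rx[j])^2 <= radius^2
      if (any(sel)) coarse[i, j] <- stats::median(img[idx[sel, , drop = FALSE]])
    }
  }
  coarse <- .fill_blocks(coarse)
  gx <- stats::approx(rx, seq_along(rx), xout = seq_len(d[2]), rule = 2)$y
  gy <- stats::approx(ry, seq_along(ry), xout = seq_len(d[1]), rule = 2)$y
  matrix(bilinear_sample(coarse, rep(gx - 1, each = d[1]),
                         rep(gy - 1, times = d[2])), d[1], d[2])
}

#' Segment cells in a background-subtracted summed-channel image
#'
#' Gaussian smooth (sigma 2), unsharp masking (subtract a sigma-25 broad
#' blur), Otsu threshold, 8-connected components, then an area filter
#' discarding fragments and aggregates. The procedure is invariant to a
#' positive rescaling of the input.
#'
#' @param sum_image background-subtracted image.
#' @param min_area,max_area area limits in px^2 (defaults 80 and 2000 at
#'   20x; scale with magnification).
#' @param smooth_sigma pre-smoothing sigma (default 2).
#' @param unsharp_sigma broad blur sigma for unsharp masking (default 25).
#' @return integer label matrix (background 0) with attribute `objects`:
#'   data.frame of label, centroid (px, 0-based), area.
#' @export
segment_cells <- function(sum_image, min_area = 80, max_area = 2000,
                          smooth_sigma = 2, unsharp_sigma = 25) {
  s <- gauss_smooth(sum_image, smooth_sigma)
  sharp <- s - gauss_smooth(s, unsharp_sigma)
  thr <- otsu_threshold(sharp)
  fg <- sharp > thr
  # structureless input (pure noise) splits near 50/50 at the Otsu cut;
  # genuine cell fields leave most of the frame as background
  if (mean(fg) > 0.45) fg[] <- FALSE
  lab <- label_components(fg)
  if (max(lab) > 0) {
    areas <- tabulate(lab[lab > 0], nbins = max(lab))
    drop <- which(areas < min_area | areas > max_area)
    if (length(drop)) lab[lab %in% drop] <- 0L
    u <- sort(unique(lab[lab > 0]))
    relab <- matrix(0L, nrow(lab), ncol(lab))
    if (length(u)) relab[lab > 0] <- match(lab[lab > 0], u)
    lab <- relab
  }
  objs <- label_objects(lab)
  attr(lab, "objects") <- objs
  lab
}

#' Object table of a label image
#'
#' @param lab integer label matrix.
#' @return data.frame with label, cx, cy (0-based px), area.
#' @export
label_objects <- function(lab) {
  n <- max(lab)
  if (n == 0)
    return(data.frame(label = integer(), cx = numeric(), cy = numeric(),
                      area = integer()))
  idx <- which(lab > 0, arr.ind = TRUE)
  l <- lab[lab > 0]
  data.frame(
    label = seq_len(n),
    cx = as.numeric(tapply(idx[, 2] - 1, l, mean)),
    cy = as.numeric(tapply(idx[, 1] - 1, l, mean)),
    area = as.integer(tabulate(l, nbins = n)))
}

#' Track objects across frames by reciprocal nearest neighbors
#'
#' Object i at frame t links to object j at frame t+1 iff j is i's
#' nearest neighbor, i is j's nearest neighbor, and their centroid
#' distance is at most `max_link`. Exact distance ties break reciprocity
#' (no link). Unlinked objects start or end tracks; tracks spanning every
#' frame are flagged complete.
#'
#' @param label_stack list of label matrices (>= 2 frames), or a list of
#'   per-frame object data.frames as from [label_objects()].
#' @param pixel_size micron per pixel.
#' @param max_link maximum link distance (micron, default 10).
#' @return data.frame with columns track, frame, label, cx, cy (0-based
#'   px), cx_um, cy_um, area, complete.
#' @export
track_cells <- function(label_stack, pixel_size = 0.325, max_link = 10) {
  if (length(label_stack) < 2) stop("tracking requires >= 2 frames")
  objs <- lapply(label_stack, function(f)
    if (is.data.frame(f)) f else
      (attr(f, "objects") %||% label_objects(f)))
  nT <- length(objs)
  # per-frame object tables with track assignment
  for (t in seq_len(nT)) objs[[t]]$track <- NA_integer_
  next_track <- 1L
  if (nrow(objs[[1]]) > 0) {
    objs[[1]]$track <- seq_len(nrow(objs[[1]]))
    next_track <- nrow(objs[[1]]) + 1L
  }
  for (t in seq_len(nT - 1)) {
    links <- reciprocal_nn_links(
      objs[[t]][, c("cx", "cy")], objs[[t + 1]][, c("cx", "cy")],
      max_dist = max_link / pixel_size)
    if (nrow(objs[[t + 1]]) > 0) {
      for (k in seq_len(nrow(links)))
        objs[[t + 1]]$track[links$j[k]] <- objs[[t]]$track[links$i[k]]
      new <- which(is.na(objs[[t + 1]]$track))
      if (length(new)) {
        objs[[t + 1]]$track[new] <- next_track + seq_along(new) - 1L
        next_track <- next_track + length(new)
      }
    }
  }
  rows <- do.call(rbind, lapply(seq_len(nT), function(t) {
    o <- objs[[t]]
    if (nrow(o) == 0) return(NULL)
    data.frame(track = o$track, frame = t, label = o$label,
               cx = o$cx, cy = o$cy,
               cx_um = o$cx * pixel_size, cy_um = o$cy * pixel_size,
               area = o$area)
  }))
  if (is.null(rows))
    return(data.frame(track = integer(), frame = integer(),
                      label = integer(), cx = numeric(), cy = numeric(),
                      cx_um = numeric(), cy_um = numeric(),
                      area = integer(), complete = logical()))
  span <- tapply(rows$frame, rows$track, function(f) length(unique(f)))
  rows$complete <- span[as.character(rows$track)] == nT
  rows[order(rows$track, rows$frame), ]
}

#' Reciprocal nearest-neighbor links between two point sets
#'
#' @param a,b data.frames/matrices with columns cx, cy (or two columns).
#' @param max_dist maximum link distance (same units as coordinates).
#' @return data.frame with indices `i` (into a), `j` (into b), `dist`.
#' @export
reciprocal_nn_links <- function(a, b, max_dist = Inf) {
  a <- as.matrix(a); b <- as.matrix(b)
  empty <- data.frame(i = integer(), j = integer(), dist = numeric())
  if (nrow(a) == 0 || nrow(b) == 0) return(empty)
  dm <- outer(a[, 1], b[, 1], "-")^2 + outer(a[, 2], b[, 2], "-")^2
  dm <- sqrt(dm)
  links <- empty
  for (i in seq_len(nrow(a))) {
    j <- which(dm[i, ] == min(dm[i, ]))
    if (length(j) != 1) next           # tie at i's end: no link
    back <- which(dm[, j] == min(dm[, j]))
    if (length(back) != 1 || back != i) next
    if (dm[i, j] > max_dist) next
    links <- rbind(links, data.frame(i = i, j = j, dist = dm[i, j]))
  }
  links
}
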