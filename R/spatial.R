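# Spatial signal profiling: where activity sits relative to the leading
# edge (geodesic distance-from-protrusion profiles) and relative to a
# focal stimulation site (concentric 1-micron radial bins), plus the
# cell screens both analyses rely on.

#' Detect the protruding leading-edge region between consecutive frames
#'
#' Candidate pixels are mask(t+1) minus mask(t); the largest 8-connected
#' component is kept, and retained only if every pixel lies within one
#' pixel (8-neighborhood dilation) of the protrusion defined from both
#' the previous and the following frame pair. First/last frame pairs have
#' a missing neighbor and yield no protrusion unless `require_neighbors`
#' is disabled.
#'
#' @param mask_t,mask_t1 logical masks of one tracked cell at consecutive
#'   frames.
#' @param prev_protrusion,next_protrusion neighbor protrusion masks
#'   (logical matrices) or NULL.
#' @param require_neighbors enforce the temporal-consistency test
#'   (default TRUE).
#' @return logical protrusion mask (all-FALSE when rejected or empty).
#' @export
detect_protrusion <- function(mask_t, mask_t1, prev_protrusion = NULL,
                              next_protrusion = NULL,
                              require_neighbors = TRUE) {
  cand <- mask_t1 & !mask_t
  if (!any(cand)) return(cand)
  lab <- label_components(cand)
  areas <- tabulate(lab[lab > 0], nbins = max(lab))
  keep <- which.max(areas)
  prot <- lab == keep
  if (require_neighbors) {
    if (is.null(prev_protrusion) || is.null(next_protrusion))
      return(matrix(FALSE, nrow(cand), ncol(cand)))
    ok_prev <- .within_one_pixel(prot, prev_protrusion)
    ok_next <- .within_one_pixel(prot, next_protrusion)
    if (!ok_prev || !ok_next)
      return(matrix(FALSE, nrow(cand), ncol(cand)))
  }
  prot
}

# `a` lies within one pixel of `b`: some pixel of `a` touches the
# 8-neighborhood dilation of `b` (a cell advancing a few pixels per frame
# produces adjacent, non-nested, crescents; requiring full containment
# would reject every moving cell)
.within_one_pixel <- function(a, b) {
  if (!any(b)) return(FALSE)
  any(a & .dilate1(b))
}

.dilate1 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  out <- m
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    s <- matrix(FALSE, nr, nc)
    rs <- max(1, 1 + dr):min(nr, nr + dr)
    cs <- max(1, 1 + dc):min(nc, nc + dc)
    s[rs, cs] <- m[rs - dr, cs - dc]
    out <- out | s
  }
  out
}

#' Geodesic distance from a source set within a mask
#'
#' Shortest within-mask path length using 8-connected steps with costs 1
#' (edge neighbors) and sqrt(2) (corner neighbors), i.e. quasi-Euclidean
#' chamfer distance, converted to micron. Paths cannot cross background.
#' Computed by repeated forward/backward chamfer sweeps until
#' convergence, which yields the exact shortest-path distance on this
#' graph.
#'
#' @param mask logical cell mask.
#' @param source logical source mask (subset of `mask`), e.g. a
#'   protrusion.
#' @param pixel_size micron per pixel (default 1: distances in pixels).
#' @return numeric matrix: distance in micron inside the mask, `NA`
#'   outside; unreachable mask pixels are `Inf`.
#' @export
geodesic_distance <- function(mask, source, pixel_size = 1) {
  if (!any(source)) stop("empty source set")
  if (any(source & !mask)) stop("source must lie inside the mask")
  nr <- nrow(mask); nc <- ncol(mask)
  d <- matrix(Inf, nr, nc)
  d[source] <- 0
  s2 <- sqrt(2)
  # horizontal propagation within contiguous mask runs of one row:
  # d[c] = min_{k <= c in run} d[k] + (c - k), via a cummin identity
  run_min <- function(v, m) {
    r <- rle(m)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (k in which(r$values)) {
      a <- starts[k]; b <- ends[k]
      idx <- seq_len(b - a + 1)
      v[a:b] <- cummin(v[a:b] - idx) + idx
    }
    v
  }
  repeat {
    changed <- FALSE
    for (pass in 1:2) {
      rows <- if (pass == 1) seq_len(nr) else rev(seq_len(nr))
      for (r in rows) {
        mrow <- mask[r, ]
        if (!any(mrow)) next
        pr <- r - (if (pass == 1) 1 else -1)
        cand <- d[r, ]
        if (pr >= 1 && pr <= nr) {
          prev <- d[pr, ]
          prev[!mask[pr, ]] <- Inf
          cand <- pmin(cand, prev + 1,
                       c(Inf, prev[-nc] + s2),
                       c(prev[-1] + s2, Inf))
        }
        cand[!mrow] <- d[r, !mrow]
        cand <- run_min(cand, mrow)                      # left to right
        cand <- rev(run_min(rev(cand), rev(mrow)))       # right to left
        if (any(cand < d[r, ])) changed <- TRUE
        d[r, ] <- cand
      }
    }
    if (!changed) break
  }
  d[!mask] <- NA
  d * pixel_size
}

#' Mean ratio versus geodesic distance from the leading edge
#'
#' Pools valid ratio pixels across frames (and cells) by geodesic
#' distance from the protrusion, averages per bin, and normalizes the
#' profile to 1 at the leading edge (distance 0).
#'
#' @param rframes list of `fret_ratio_frame` (or ratio matrices).
#' @param masks list of logical cell masks (one per frame).
#' @param protrusions list of logical protrusion masks; frames with an
#'   empty protrusion are skipped.
#' @param pixel_size micron per pixel.
#' @param bin_width bin width in micron (default 1).
#' @param normalize divide by the first (leading-edge) bin (default TRUE).
#' @return data.frame with `distance` (bin lower edge, micron), `mean_ratio`,
#'   `n_px`; empty bins are missing rows.
#' @export
edge_distance_profile <- function(rframes, masks, protrusions, pixel_size,
                                  bin_width = 1, normalize = TRUE) {
  dists <- c(); vals <- c()
  for (fr in seq_along(rframes)) {
    prot <- protrusions[[fr]]
    if (is.null(prot) || !any(prot)) next
    ratio <- if (inherits(rframes[[fr]], "fret_ratio_frame"))
      rframes[[fr]]$ratio else rframes[[fr]]
    mask <- masks[[fr]] | prot
    # crop to the mask bounding box (plus margin) before the geodesic
    ridx <- range(which(rowSums(mask) > 0))
    cidx <- range(which(colSums(mask) > 0))
    rs <- max(1, ridx[1] - 1):min(nrow(mask), ridx[2] + 1)
    cs <- max(1, cidx[1] - 1):min(ncol(mask), cidx[2] + 1)
    g <- geodesic_distance(mask[rs, cs], prot[rs, cs], pixel_size)
    rt <- ratio[rs, cs]
    ok <- is.finite(g) & is.finite(rt)
    dists <- c(dists, g[ok]); vals <- c(vals, rt[ok])
  }
  if (length(vals) == 0) stop("no frames with a defined protrusion")
  bin <- floor(dists / bin_width)
  agg <- tapply(vals, bin, mean)
  out <- data.frame(distance = as.numeric(names(agg)) * bin_width,
                    mean_ratio = as.numeric(agg),
                    n_px = as.integer(tapply(vals, bin, length)))
  out <- out[order(out$distance), ]
  if (normalize) {
    if (out$distance[1] != 0) stop("no pixels at the leading edge")
    out$mean_ratio <- out$mean_ratio / out$mean_ratio[1]
  }
  rownames(out) <- NULL
  out
}

#' Screen a center-stimulated cell for analysis
#'
#' Rejects the cell if the stimulation pixel is not inside the cell mask
#' at the stimulation frame, if it lies less than `min_edge_px` pixels
#' from the cell edge (Euclidean distance-to-background), or if any
#' post-stimulus centroid displacement from the stimulation-frame
#' centroid exceeds `max_travel` micron.
#'
#' @param track data.frame for one track (columns frame, cx_um, cy_um).
#' @param masks list of per-frame logical masks of the cell.
#' @param frap_pixel 0-based c(x, y) stimulation pixel.
#' @param stim_frame frame index at which the stimulus is applied.
#' @param pixel_size micron per pixel.
#' @param max_travel maximum post-stimulus centroid travel (micron,
#'   default 4).
#' @param min_edge_px minimum distance from the cell edge (pixels,
#'   default 4).
#' @return list with `keep` (logical) and `reason` (string; "" if kept).
#' @export
screen_center_stim_cell <- function(track, masks, frap_pixel, stim_frame,
                                    pixel_size, max_travel = 4,
                                    min_edge_px = 4) {
  m <- masks[[stim_frame]]
  r <- frap_pixel[2] + 1; c <- frap_pixel[1] + 1
  if (r < 1 || r > nrow(m) || c < 1 || c > ncol(m) || !m[r, c])
    return(list(keep = FALSE, reason = "stimulus_outside_mask"))
  edge_d <- EBImage::distmap(EBImage::Image(m * 1))
  if (edge_d[r, c] < min_edge_px)
    return(list(keep = FALSE, reason = "stimulus_near_edge"))
  tr <- track[order(track$frame), ]
  ref <- tr[tr$frame == stim_frame, c("cx_um", "cy_um")]
  post <- tr[tr$frame > stim_frame, , drop = FALSE]
  if (nrow(post) > 0) {
    disp <- sqrt((post$cx_um - ref$cx_um)^2 + (post$cy_um - ref$cy_um)^2)
    if (any(disp > max_travel))
      return(list(keep = FALSE, reason = "excess_motion"))
  }
  list(keep = TRUE, reason = "")
}

#' Concentric radial response profile around a stimulation site
#'
#' In-mask pixels are binned by Euclidean distance from the stimulation
#' pixel into 1-micron annuli (half-open [k-1, k) micron, pixel-center
#' distances). Per bin the ratio is mean acceptor / mean donor, with the
#' ratio correction applied to the acceptor beforehand; the fold change
#' divides each bin by the same bin in the frame immediately preceding
#' stimulation. Bins with fewer than `min_px` valid pixels are reported
#' missing (`NA`).
#'
#' @param donor_frames,acceptor_frames lists of corrected, aligned,
#'   background-subtracted channel images (registered to a common origin;
#'   stage offsets already applied).
#' @param masks list of per-frame logical cell masks.
#' @param frap_pixel 0-based c(x, y) stimulation pixel.
#' @param pre_frame index of the frame immediately preceding stimulation.
#' @param pixel_size micron per pixel.
#' @param ratio_correction matrix dividing the acceptor (default none).
#' @param bin_width micron (default 1).
#' @param min_px minimum valid pixels per reported bin (default 5).
#' @return data.frame with `frame`, `bin` (1 = nearest), `r_lo`, `r_hi`,
#'   `n_px`, `ratio`, `fold_change`, `coverage` (fraction of the full
#'   annulus area inside the mask).
#' @export
radial_profile <- function(donor_frames, acceptor_frames, masks,
                           frap_pixel, pre_frame, pixel_size,
                           ratio_correction = NULL, bin_width = 1,
                           min_px = 5) {
  fs <- dim(donor_frames[[1]])
  x <- matrix(rep(0:(fs[2] - 1), each = fs[1]), fs[1], fs[2])
  y <- matrix(rep(0:(fs[1] - 1), times = fs[2]), fs[1], fs[2])
  r <- sqrt(((x - frap_pixel[1]) * pixel_size)^2 +
              ((y - frap_pixel[2]) * pixel_size)^2)
  bin_of <- floor(r / bin_width) + 1L
  out <- list()
  for (fr in seq_along(donor_frames)) {
    don <- donor_frames[[fr]]
    acc <- acceptor_frames[[fr]]
    if (!is.null(ratio_correction)) acc <- acc / ratio_correction
    ok <- masks[[fr]] & is.finite(don) & is.finite(acc) & don > 0
    if (!any(ok)) next
    bins <- sort(unique(bin_of[ok]))
    for (b in bins) {
      sel <- ok & bin_of == b
      n <- sum(sel)
      annulus_px <- sum(bin_of == b)
      out[[length(out) + 1]] <- data.frame(
        frame = fr, bin = b,
        r_lo = (b - 1) * bin_width, r_hi = b * bin_width,
        n_px = n,
        ratio = if (n >= min_px) mean(acc[sel]) / mean(don[sel]) else NA_real_,
        coverage = n / annulus_px)
    }
  }
  prof <- do.call(rbind, out)
  pre <- prof[prof$frame == pre_frame, c("bin", "ratio")]
  names(pre)[2] <- "pre_ratio"
  prof <- merge(prof, pre, by = "bin", all.x = TRUE, sort = FALSE)
  prof$fold_change <- prof$ratio / prof$pre_ratio
  prof$pre_ratio <- NULL
  prof[order(prof$frame, prof$bin), ]
}

#' Select the perimeter pixel closest to a target angle
#'
#' Among outer-perimeter pixels of the mask, returns the one whose angle
#' from the centroid is closest to `target_angle`; ties are broken by the
#' larger centroid distance. Angles follow the mathematical convention:
#' counter-clockwise from +x with the physical y axis pointing up (image
#' row axis points down).
#'
#' @param mask logical cell mask.
#' @param centroid 0-based c(x, y); defaults to the mask centroid.
#' @param target_angle degrees.
#' @return 0-based c(x, y) of the selected perimeter pixel.
#' @export
select_edge_target <- function(mask, centroid = NULL, target_angle = 0) {
  if (!any(mask)) stop("empty mask")
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 1) stop("degenerate single-pixel mask")
  if (is.null(centroid))
    centroid <- c(mean(idx[, 2] - 1), mean(idx[, 1] - 1))
  interior <- .erode1(mask)
  per <- which(mask & !interior, arr.ind = TRUE)
  px <- per[, 2] - 1; py <- per[, 1] - 1
  dx <- px - centroid[1]
  dy <- -(py - centroid[2])   # physical y up
  ang <- atan2(dy, dx) * 180 / pi
  diff <- abs(((ang - target_angle + 180) %% 360) - 180)
  dist <- sqrt(dx^2 + dy^2)
  best <- which(diff == min(diff))
  if (length(best) > 1) best <- best[which.max(dist[best])]
  c(px[best], py[best])
}

.erode1 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  out <- m
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    s <- matrix(FALSE, nr, nc)
    rs <- max(1, 1 + dr):min(nr, nr + dr)
    cs <- max(1, 1 + dc):min(nc, nc + dc)
    s[rs, cs] <- m[rs - dr, cs - dc]
    out <- out & s
  }
  out
}
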