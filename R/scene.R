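# Ground-truth synthetic scenes.
#
# A scene holds moving, deformable cells with a known per-pixel activity
# field, ready to be rendered into dual-camera image stacks. Every
# downstream stage of the pipeline is validated against these known
# truths. Cells are deformable disks (low-order Fourier boundary
# perturbation) moving by a persistent random walk whose heading follows
# an Ornstein-Uhlenbeck process; activity follows the feedback kinetics in
# kinetics_params().

#' Scene configuration
#'
#' @param field_shape c(rows, cols) of the imaging field in pixels.
#' @param pixel_size micron per pixel (default 0.325, a 6.5 micron camera
#'   pixel behind a 20x objective).
#' @param frame_interval seconds between frames (default 1.5).
#' @param n_frames number of frames.
#' @param n_cells number of cells to place.
#' @param cell_radius mean cell radius (micron).
#' @param radius_jitter relative Fourier boundary perturbation amplitude.
#' @param speed mean migration speed (micron/s).
#' @param persistence_time OU correlation time of the heading (s).
#' @param dead_fraction fraction of cells rendered as dead (low constant
#'   ratio, no response).
#' @param baseline_ratio acceptor/donor ratio of resting healthy cells.
#' @param dead_ratio constant ratio of dead cells (must be < 0.8 so the
#'   pixel filters catch them).
#' @param sensor_density expected summed-channel photon count per interior
#'   cell pixel.
#' @param response_amplitude relative ratio modulation at A = 1 (default
#'   0.11, the dynamic-range scale of the red/far-red sensor pair).
#' @param programmed_amplitude optional calibrated response amplitude: the
#'   modulation is rescaled so that the mean modulation over the standard
#'   peak window (4.5-10.5 s after the first stimulus) equals this value.
#'   Used by recovery tests where ground truth must be stated in the same
#'   units the analysis measures.
#' @param stimuli list of [stimulus_event()].
#' @param kinetics [kinetics_params()].
#' @param edge_width soft-edge width of the cell boundary (pixels).
#' @return list of class `fret_scene_params`.
#' @export
scene_params <- function(field_shape = c(160, 160), pixel_size = 0.325,
                         frame_interval = 1.5, n_frames = 20, n_cells = 6,
                         cell_radius = 6, radius_jitter = 0.12,
                         speed = 0.08, persistence_time = 60,
                         dead_fraction = 0, baseline_ratio = 1.0,
                         dead_ratio = 0.6, sensor_density = 3000,
                         response_amplitude = 0.11,
                         programmed_amplitude = NULL,
                         stimuli = list(), kinetics = kinetics_params(),
                         edge_width = 1.0) {
  p <- as.list(environment())
  stopifnot(n_frames >= 1, pixel_size > 0, n_cells >= 0,
            dead_ratio < 0.8, sensor_density > 0)
  class(p) <- "fret_scene_params"
  p
}

# Boundary radius (micron) of a deformed disk at polar angles phi.
.cell_radius_at <- function(phi, shape) {
  r <- shape$r0
  for (k in seq_along(shape$amp))
    r <- r + shape$r0 * shape$amp[k] * cos((k + 1) * phi + shape$phase[k])
  r
}

# Soft coverage (0..1) of the cell over field pixels; returns a list with
# pixel indices (coverage > 0.5 defines the mask), coverage values, and
# the local pixel coordinates.
.rasterize_cell <- function(center_um, shape, field_shape, pixel_size,
                            edge_width) {
  rmax_px <- (shape$r0 * (1 + sum(abs(shape$amp))) / pixel_size) + 2
  cx <- center_um[1] / pixel_size; cy <- center_um[2] / pixel_size
  x0 <- max(0, floor(cx - rmax_px)); x1 <- min(field_shape[2] - 1, ceiling(cx + rmax_px))
  y0 <- max(0, floor(cy - rmax_px)); y1 <- min(field_shape[1] - 1, ceiling(cy + rmax_px))
  if (x1 < x0 || y1 < y0) return(NULL)
  xs <- x0:x1; ys <- y0:y1
  X <- rep(xs, each = length(ys)); Y <- rep(ys, times = length(xs))
  dx <- (X - cx) * pixel_size; dy <- (Y - cy) * pixel_size
  d <- sqrt(dx^2 + dy^2)
  phi <- atan2(dy, dx)
  rb <- .cell_radius_at(phi, shape)
  cov <- pmin(pmax((rb - d) / (edge_width * pixel_size) + 0.5, 0), 1)
  keep <- cov > 0
  if (!any(keep)) return(NULL)
  idx <- (X[keep]) * field_shape[1] + Y[keep] + 1  # column-major linear index
  list(idx = as.integer(idx), coverage = cov[keep],
       x = X[keep], y = Y[keep])
}

#' Generate a ground-truth scene
#'
#' Places non-overlapping cells, simulates their motion and shape, and
#' integrates the activity kinetics per cell (per pixel for focal
#' stimuli). Deterministic for a fixed seed; each cell consumes its own
#' derived random stream so per-cell results do not depend on generation
#' order.
#'
#' @param params [scene_params()].
#' @param seed integer master seed.
#' @return object of class `fret_scene`: list with `params`, `seed`,
#'   `times`, `stimuli`, `amp_eff`, and `cells` (each cell a list with
#'   per-frame centroids in micron, pixel data, activity matrix, flags).
#' @export
make_scene <- function(params, seed = 1L) {
  stopifnot(inherits(params, "fret_scene_params"))
  fs <- params$field_shape
  px <- params$pixel_size
  times <- (seq_len(params$n_frames) - 1) * params$frame_interval
  for (s in params$stimuli) {
    if (s$time < 0 || s$time > params$n_frames * params$frame_interval)
      stop("stimulus time outside the imaging interval")
    if (s$kind == "focal") {
      if (s$target[1] < 0 || s$target[1] > fs[2] - 1 ||
          s$target[2] < 0 || s$target[2] > fs[1] - 1)
        stop("focal stimulus target outside the field")
    }
  }
  margin_um <- params$cell_radius * (1 + 3 * params$radius_jitter) + 1
  lo <- c(margin_um, margin_um)
  hi <- c(fs[2] - 1, fs[1] - 1) * px - margin_um
  if (any(hi <= lo) && params$n_cells > 0)
    stop("field too small for the requested cell radius")

  # non-overlapping placement with bounded retries
  centers <- with_seed(derive_seed(seed, 1), {
    placed <- matrix(numeric(0), 0, 2)
    tries <- 0
    while (nrow(placed) < params$n_cells) {
      cand <- c(stats::runif(1, lo[1], hi[1]), stats::runif(1, lo[2], hi[2]))
      ok <- nrow(placed) == 0 ||
        all(sqrt(rowSums((placed - matrix(cand, nrow(placed), 2,
                                          byrow = TRUE))^2)) >
              2.4 * params$cell_radius)
      if (ok) placed <- rbind(placed, cand)
      tries <- tries + 1
      if (tries > 2000 * max(params$n_cells, 1))
        stop("could not place cells without overlap: configuration too dense")
    }
    placed
  })

  n_dead <- round(params$dead_fraction * params$n_cells)
  dead <- with_seed(derive_seed(seed, 2),
                    sample(seq_len(max(params$n_cells, 1)),
                           size = n_dead))

  # calibrated response amplitude (peak-window definition)
  amp_eff <- params$response_amplitude
  if (!is.null(params$programmed_amplitude)) {
    if (length(params$stimuli) == 0)
      amp_eff <- 0
    else {
      t1 <- min(vapply(params$stimuli, function(s) s$time, 0))
      sol <- integrate_activity(params$kinetics, params$stimuli, times, g = 1)
      ss <- kinetics_steady_state(params$kinetics)
      mod <- sol$A[1, ] - ss$A
      # peak window on the analysis time axis: relative to the last frame
      # before stimulation
      t0 <- if (any(times < t1)) max(times[times < t1]) else t1
      inP <- times - t0 >= 4.5 & times - t0 <= 10.5
      mP <- mean(mod[inP])
      if (!is.finite(mP) || mP <= 0)
        stop("cannot calibrate programmed amplitude: no response in peak window")
      # exact peak-window fold change: (1 + a*(ss + mP)) / (1 + a*ss) = 1 + prog
      prog <- params$programmed_amplitude
      amp_eff <- prog / (mP - prog * ss$A)
    }
  }

  cells <- vector("list", params$n_cells)
  for (ci in seq_len(params$n_cells)) {
    cells[[ci]] <- with_seed(derive_seed(seed, 10 + ci), {
      shape <- list(
        r0 = params$cell_radius * stats::runif(1, 0.9, 1.1),
        amp = params$radius_jitter * stats::runif(4, 0.2, 1) / (1:4),
        phase = stats::runif(4, 0, 2 * pi))
      # persistent random walk: OU heading, slow speed jitter
      theta <- stats::runif(1, 0, 2 * pi)
      pos <- matrix(0, params$n_frames, 2)
      pos[1, ] <- centers[ci, ]
      dt <- params$frame_interval
      for (fr in seq_len(params$n_frames - 1)) {
        theta <- theta + sqrt(2 * dt / params$persistence_time) * stats::rnorm(1)
        step <- params$speed * dt
        cand <- pos[fr, ] + step * c(cos(theta), sin(theta))
        cand <- pmin(pmax(cand, lo), hi)
        pos[fr + 1, ] <- cand
      }
      # slow boundary phase drift so shapes evolve between frames
      drift <- stats::runif(4, -0.04, 0.04)
      is_dead <- ci %in% dead
      pix <- vector("list", params$n_frames)
      for (fr in seq_len(params$n_frames)) {
        sh <- shape
        sh$phase <- shape$phase + drift * (fr - 1)
        pix[[fr]] <- .rasterize_cell(pos[fr, ], sh, fs, px, params$edge_width)
      }
      # activity: global stimuli -> one shared trajectory; focal -> per pixel
      focal <- Filter(function(s) s$kind == "focal", params$stimuli)
      activity <- vector("list", params$n_frames)
      if (is_dead || length(params$stimuli) == 0) {
        base_A <- if (is_dead) 0 else kinetics_steady_state(params$kinetics)$A
        for (fr in seq_len(params$n_frames))
          activity[[fr]] <- rep(base_A, length(pix[[fr]]$idx))
      } else if (length(focal) == 0) {
        sol <- integrate_activity(params$kinetics, params$stimuli, times, g = 1)
        for (fr in seq_len(params$n_frames))
          activity[[fr]] <- rep(sol$A[1, fr], length(pix[[fr]]$idx))
      } else {
        # per-pixel weights from the frame-1 geometry (screened focal cells
        # move little); g evaluated in micron from the target
        p1 <- pix[[1]]
        gs <- rep(1, length(p1$idx))
        for (s in focal) {
          d2 <- ((p1$x - s$target[1]) * px)^2 + ((p1$y - s$target[2]) * px)^2
          gs <- gs * exp(-d2 / (2 * params$kinetics$spread_length^2))
        }
        sol <- integrate_activity(params$kinetics, params$stimuli, times, g = gs)
        for (fr in seq_len(params$n_frames)) {
          # map frame-1 pixels onto this frame's raster by nearest offset
          pf <- pix[[fr]]
          key1 <- paste(p1$x, p1$y)
          keyf <- paste(pf$x, pf$y)
          m <- match(keyf, key1)
          a <- sol$A[ifelse(is.na(m), 1, m), fr]
          a[is.na(m)] <- kinetics_steady_state(params$kinetics)$A
          activity[[fr]] <- a
        }
      }
      list(centroids = pos, shape = shape, pixels = pix,
           activity = activity, is_dead = is_dead,
           baseline_ratio = if (is_dead) params$dead_ratio
                            else params$baseline_ratio)
    })
  }
  structure(list(params = params, seed = as.integer(seed), times = times,
                 stimuli = params$stimuli, amp_eff = amp_eff,
                 cells = cells),
            class = "fret_scene")
}

#' @export
print.fret_scene <- function(x, ...) {
  cat("<fret_scene>", length(x$cells), "cells,",
      x$params$n_frames, "frames,",
      paste(x$params$field_shape, collapse = "x"), "px, seed", x$seed, "\n")
  invisible(x)
}

#' True cell mask of one cell at one frame
#'
#' @param scene `fret_scene`.
#' @param cell,frame indices (1-based).
#' @return logical matrix of the field shape.
#' @export
scene_cell_mask <- function(scene, cell, frame) {
  fs <- scene$params$field_shape
  m <- matrix(FALSE, fs[1], fs[2])
  p <- scene$cells[[cell]]$pixels[[frame]]
  if (!is.null(p)) m[p$idx[p$coverage > 0.5]] <- TRUE
  m
}

#' True ratio image of a scene at one frame
#'
#' Per-pixel acceptor/donor ratio implied by the ground truth (no optics,
#' no noise): baseline * (1 + amp * A). Background pixels are `NA`.
#'
#' @param scene `fret_scene`.
#' @param frame frame index.
#' @return numeric matrix with `NA` outside cells.
#' @export
scene_true_ratio <- function(scene, frame) {
  fs <- scene$params$field_shape
  out <- matrix(NA_real_, fs[1], fs[2])
  for (cell in scene$cells) {
    p <- cell$pixels[[frame]]
    if (is.null(p)) next
    keep <- p$coverage > 0.5
    out[p$idx[keep]] <-
      cell$baseline_ratio * (1 + scene$amp_eff * cell$activity[[frame]][keep])
  }
  out
}
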