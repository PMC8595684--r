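# Dual-camera image formation.
#
# Expected per-pixel photon counts follow a fixed FRET redistribution
# model: with total sensor emission S and ratio R = baseline * (1 + amp*A),
#   donor    = S * L_d / (1 + R)
#   acceptor = S * L_a * R / (1 + R)
# so donor + acceptor = S * L: FRET redistributes signal between channels
# without creating it. L is each camera's multiplicative
# illumination/sensitivity field (vignette x half-chip step x dust spot).
# The donor camera views the sample through its own coordinate system
# (true_alignment maps acceptor coordinates to donor coordinates), so the
# ideal donor image is resampled through the inverse map before camera
# effects and noise. Counts are gain * Poisson(photons) + dark offset +
# Gaussian read noise, clipped at the configured bit depth (saturation is
# clipped, never rescaled).

#' Optics and camera model for rendering
#'
#' @param field_shape c(rows, cols).
#' @param true_alignment `fret_alignment` mapping acceptor to donor
#'   coordinates (identity by default).
#' @param vignette_strength relative radial illumination droop at the field
#'   corner (same smooth field applied to both cameras).
#' @param half_chip_factor multiplicative sensitivity of the bottom half of
#'   the donor camera chip (1 = no step).
#' @param dust list(center = c(x, y) 0-based px, radius_px, depth) for a
#'   Gaussian dim spot on the donor camera, or NULL.
#' @param dark_offset counts added by camera electronics.
#' @param read_noise_sd Gaussian read noise SD (counts).
#' @param gain counts per photon.
#' @param bit_depth saturation at 2^bit_depth - 1.
#' @param bg_level expected background photon level per channel (smooth
#'   nonzero background as in empty-well images).
#' @param bg_tilt relative left-to-right linear tilt of the background.
#' @return list of class `fret_optics`.
#' @export
optics_model <- function(field_shape, true_alignment = NULL,
                         vignette_strength = 0.03,
                         half_chip_factor = 0.97,
                         dust = list(center = NULL, radius_px = 14,
                                     depth = 0.2),
                         dark_offset = 100, read_noise_sd = 3,
                         gain = 2, bit_depth = 16L, bg_level = 700,
                         bg_tilt = 0.05) {
  if (is.null(true_alignment))
    true_alignment <- alignment_model(ref_shape = field_shape)
  if (!is.null(dust) && is.null(dust$center))
    dust$center <- c(round(field_shape[2] * 0.3), round(field_shape[1] * 0.62))
  if (!is.null(dust) && (dust$depth <= 0 || dust$depth >= 1))
    stop("dust depth must be in (0, 1)")
  if (gain <= 0) stop("gain must be > 0")
  structure(list(field_shape = as.integer(field_shape),
                 true_alignment = true_alignment,
                 vignette_strength = vignette_strength,
                 half_chip_factor = half_chip_factor, dust = dust,
                 dark_offset = dark_offset, read_noise_sd = read_noise_sd,
                 gain = gain, bit_depth = as.integer(bit_depth),
                 bg_level = bg_level, bg_tilt = bg_tilt),
            class = "fret_optics")
}

#' Identity optics (no misalignment, artifacts, offsets, or noise terms)
#'
#' @param field_shape c(rows, cols).
#' @return `fret_optics` with unit fields and zero offsets.
#' @export
identity_optics <- function(field_shape) {
  optics_model(field_shape, vignette_strength = 0, half_chip_factor = 1,
               dust = NULL, dark_offset = 0, read_noise_sd = 0, gain = 1,
               bg_level = 0, bg_tilt = 0)
}

# Multiplicative illumination/sensitivity field of one camera.
.camera_field <- function(optics, camera = c("donor", "acceptor")) {
  camera <- match.arg(camera)
  fs <- optics$field_shape
  x <- matrix(rep(0:(fs[2] - 1), each = fs[1]), fs[1], fs[2])
  y <- matrix(rep(0:(fs[1] - 1), times = fs[2]), fs[1], fs[2])
  cx <- (fs[2] - 1) / 2; cy <- (fs[1] - 1) / 2
  r2 <- ((x - cx)^2 + (y - cy)^2) / (cx^2 + cy^2)
  L <- 1 - optics$vignette_strength * r2
  if (camera == "donor") {
    if (optics$half_chip_factor != 1) {
      mid <- fs[1] %/% 2
      L[(mid + 1):fs[1], ] <- L[(mid + 1):fs[1], ] * optics$half_chip_factor
    }
    if (!is.null(optics$dust)) {
      d2 <- (x - optics$dust$center[1])^2 + (y - optics$dust$center[2])^2
      L <- L * (1 - optics$dust$depth * exp(-d2 / (2 * optics$dust$radius_px^2)))
    }
  }
  L
}

# Smooth nonzero background photon field (per channel, sample coordinates).
.background_field <- function(optics) {
  fs <- optics$field_shape
  x <- matrix(rep(0:(fs[2] - 1), each = fs[1]), fs[1], fs[2])
  optics$bg_level * (1 + optics$bg_tilt * (x / max(fs[2] - 1, 1) - 0.5))
}

# Ideal (sample-coordinate) expected photon images for one frame,
# optionally with a bleach-fraction field applied to the sensor pool.
.ideal_channels <- function(scene, frame, optics, bleach_b = NULL,
                            bleach_alpha = 0) {
  fs <- scene$params$field_shape
  S <- matrix(0, fs[1], fs[2])
  R <- matrix(1, fs[1], fs[2])
  for (cell in scene$cells) {
    p <- cell$pixels[[frame]]
    if (is.null(p)) next
    S[p$idx] <- S[p$idx] + scene$params$sensor_density * p$coverage
    R[p$idx] <- cell$baseline_ratio *
      (1 + scene$amp_eff * cell$activity[[frame]])
  }
  don <- S / (1 + R)
  acc <- S * R / (1 + R)
  if (!is.null(bleach_b)) {
    don <- don * (1 - bleach_b)
    acc <- acc * (1 - bleach_b) * (1 - bleach_alpha * bleach_b)
  }
  bg <- .background_field(optics)
  list(donor = don + bg, acceptor = acc + bg)
}

# Camera pipeline: Poisson shot noise on photons, gain, dark offset,
# Gaussian read noise, saturation clip.
.expose <- function(photons, optics, noise) {
  counts <- if (noise) {
    optics$gain * stats::rpois(length(photons), photons) +
      optics$dark_offset +
      stats::rnorm(length(photons), 0, optics$read_noise_sd)
  } else {
    optics$gain * photons + optics$dark_offset
  }
  counts <- matrix(counts, nrow(photons), ncol(photons))
  pmin(pmax(counts, 0), 2^optics$bit_depth - 1)
}

#' Render a scene into a dual-channel image stack
#'
#' @param scene `fret_scene` from [make_scene()].
#' @param optics `fret_optics`.
#' @param noise render shot/read noise (TRUE) or expected images (FALSE).
#' @param seed RNG seed for the noise draws (default derived from the
#'   scene seed, so identical scene + optics render identically).
#' @return `fret_stack`: list with `donor`, `acceptor` (lists of
#'   matrices), `times`, `pixel_size`, `frame_interval`, `stimuli`.
#' @export
render_frames <- function(scene, optics, noise = TRUE,
                          seed = derive_seed(scene$seed, 77)) {
  stopifnot(inherits(scene, "fret_scene"), inherits(optics, "fret_optics"))
  if (!alignment_invertible(optics$true_alignment))
    stop("true_alignment is not invertible over the field")
  .render_stack(scene, optics, noise, seed, bleach = NULL)
}

#' Render a scene with a diffusing photobleached sensor pool
#'
#' After each focal stimulus a Gaussian pool of bleached (dark) sensor is
#' created at the target and spreads by free diffusion; the bleached
#' fraction b(x, t) reduces sensor emission with a channel asymmetry
#' `alpha`, biasing the observed ratio by the factor (1 - alpha * b).
#'
#' @param scene `fret_scene` containing focal stimuli.
#' @param optics `fret_optics`.
#' @param bleach `fret_bleach_model` (see [bleach_model()]); its amplitude
#'   is scaled linearly by each stimulus power relative to
#'   `bleach$calibration_power`.
#' @param noise,seed as in [render_frames()]; with `bleach` amplitude 0
#'   the output is identical to [render_frames()] under the same seed.
#' @return `fret_stack`.
#' @export
render_bleach <- function(scene, optics, bleach, noise = TRUE,
                          seed = derive_seed(scene$seed, 77)) {
  stopifnot(inherits(bleach, "fret_bleach_model"))
  .render_stack(scene, optics, noise, seed, bleach = bleach)
}

.render_stack <- function(scene, optics, noise, seed, bleach) {
  fs <- scene$params$field_shape
  nF <- scene$params$n_frames
  Ld <- .camera_field(optics, "donor")
  La <- .camera_field(optics, "acceptor")
  # donor-camera sampling coordinates: inverse of the acceptor->donor map
  grid <- .full_grid(fs[1], fs[2])
  inv <- invert_alignment(optics$true_alignment, grid$x, grid$y)
  donor <- vector("list", nF); acceptor <- vector("list", nF)
  for (fr in seq_len(nF)) {
    b <- NULL; alpha <- 0
    if (!is.null(bleach)) {
      b <- bleach_field_at(bleach, scene, fr)
      alpha <- bleach$alpha
      if (any(b < 0 | b > 1)) stop("bleach fraction outside [0, 1]")
    }
    ideal <- .ideal_channels(scene, fr, optics, b, alpha)
    don_cam <- matrix(bilinear_sample(ideal$donor, inv$x, inv$y), fs[1], fs[2])
    don_cam[is.na(don_cam)] <- .background_field(optics)[is.na(don_cam)]
    donor[[fr]] <- with_seed(derive_seed(seed, fr, 1),
                             .expose(don_cam * Ld, optics, noise))
    acceptor[[fr]] <- with_seed(derive_seed(seed, fr, 2),
                                .expose(ideal$acceptor * La, optics, noise))
  }
  structure(list(donor = donor, acceptor = acceptor, times = scene$times,
                 pixel_size = scene$params$pixel_size,
                 frame_interval = scene$params$frame_interval,
                 stimuli = scene$stimuli, field_shape = fs,
                 bit_depth = optics$bit_depth),
            class = "fret_stack")
}

#' @export
print.fret_stack <- function(x, ...) {
  cat("<fret_stack>", length(x$donor), "frames,",
      paste(x$field_shape, collapse = "x"), "px,",
      x$pixel_size, "um/px\n")
  invisible(x)
}

#' Render a calibration stack (dark frames, uniform dye, or empty well)
#'
#' @param kind "dark" (no illumination), "dye" (uniform bright field), or
#'   "empty" (background only).
#' @param optics `fret_optics`.
#' @param n_frames frames to render.
#' @param camera "donor" or "acceptor".
#' @param dye_level expected photon level of the uniform dye.
#' @param seed RNG seed.
#' @return list of frame matrices.
#' @export
render_calibration <- function(kind = c("dark", "dye", "empty"), optics,
                               n_frames = 79L,
                               camera = c("donor", "acceptor"),
                               dye_level = 5000, seed = 1L) {
  kind <- match.arg(kind); camera <- match.arg(camera)
  fs <- optics$field_shape
  L <- .camera_field(optics, camera)
  photons <- switch(kind,
    dark = matrix(0, fs[1], fs[2]),
    dye = dye_level * L,
    empty = .background_field(optics) * L)
  lapply(seq_len(n_frames), function(fr)
    with_seed(derive_seed(seed, kind == "dye", fr,
                          camera == "donor"),
              .expose(photons, optics, noise = TRUE)))
}
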