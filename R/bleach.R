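# Diffusing photobleached sensor pool.
#
# Focal optogenetic stimulation photobleaches a Gaussian pool of sensor at
# the target site. The bleached fraction b(x, t) starts as
# b0 * exp(-r^2 / (2 sigma0^2)) and spreads by free 2-D membrane diffusion:
#   sigma^2(t) = sigma0^2 + 2 D t,  amplitude b0 * sigma0^2 / sigma^2(t)
# which conserves the total bleached amount. Because donor and acceptor
# constructs bleach asymmetrically, a bleached fraction b biases the
# observed ratio by the factor (1 - alpha * b); ratio frames are corrected
# by dividing that factor out.

#' Construct a bleach model
#'
#' @param b0 initial bleached fraction at the stimulus center, in [0, 1].
#' @param sigma0 initial Gaussian width (micron).
#' @param D diffusion coefficient (micron^2/s); default 0.5.
#' @param alpha channel-asymmetry coefficient mapping bleached fraction to
#'   ratio bias (1 - alpha*b).
#' @param calibration_power stimulus power at which `b0` was measured;
#'   amplitudes scale linearly with power / calibration_power.
#' @param center 0-based pixel c(x, y) of the calibration target
#'   (optional; per-stimulus targets override it).
#' @return list of class `fret_bleach_model`.
#' @export
bleach_model <- function(b0 = 0.3, sigma0 = 1.5, D = 0.5, alpha = 1,
                         calibration_power = 37, center = NULL) {
  if (b0 < 0 || b0 > 1) stop("b0 must be in [0, 1]")
  if (sigma0 <= 0 || D < 0) stop("sigma0 must be > 0 and D >= 0")
  structure(list(b0 = b0, sigma0 = sigma0, D = D, alpha = alpha,
                 calibration_power = calibration_power, center = center),
            class = "fret_bleach_model")
}

#' Propagate the bleach pool to time t
#'
#' Evaluates the free-diffusion closed form on a pixel grid.
#'
#' @param model `fret_bleach_model`.
#' @param t time since bleaching (s), >= 0.
#' @param field_shape c(rows, cols).
#' @param pixel_size micron per pixel.
#' @param center 0-based pixel c(x, y); defaults to `model$center`.
#' @param power stimulus power; amplitude is scaled by
#'   `power / calibration_power`.
#' @return bleach-fraction matrix (values in [0, 1]).
#' @export
propagate_bleach <- function(model, t, field_shape, pixel_size,
                             center = model$center,
                             power = model$calibration_power) {
  stopifnot(t >= 0, !is.null(center))
  s2 <- model$sigma0^2 + 2 * model$D * t
  amp <- model$b0 * (power / model$calibration_power) * model$sigma0^2 / s2
  x <- matrix(rep(0:(field_shape[2] - 1), each = field_shape[1]),
              field_shape[1], field_shape[2])
  y <- matrix(rep(0:(field_shape[1] - 1), times = field_shape[2]),
              field_shape[1], field_shape[2])
  r2 <- ((x - center[1]) * pixel_size)^2 + ((y - center[2]) * pixel_size)^2
  amp * exp(-r2 / (2 * s2))
}

#' Total bleach-fraction field of a scene at a frame
#'
#' Sums the contributions of all focal stimuli delivered before the frame
#' time, clipped at the physical bound b <= 1.
#'
#' @param model `fret_bleach_model`.
#' @param scene `fret_scene` (supplies stimuli, field shape, pixel size).
#' @param frame frame index (1-based).
#' @return bleach-fraction matrix.
#' @export
bleach_field_at <- function(model, scene, frame) {
  fs <- scene$params$field_shape
  t_fr <- scene$times[frame]
  b <- matrix(0, fs[1], fs[2])
  for (s in scene$stimuli) {
    if (s$kind != "focal" || s$time > t_fr) next
    b <- b + propagate_bleach(model, t_fr - s$time, fs,
                              scene$params$pixel_size,
                              center = s$target, power = s$power)
  }
  pmin(b, 1)
}

#' Fit the initial bleach profile from a pre/post image pair
#'
#' Least-squares fit of the radial Gaussian dip
#' 1 - b0 * exp(-r^2 / (2 sigma0^2)) to the post/pre intensity ratio.
#'
#' @param post_bleach,pre_bleach co-registered intensity images.
#' @param center 0-based pixel c(x, y) of the bleach target.
#' @param pixel_size micron per pixel.
#' @param fit_radius radius (micron) of pixels entering the fit.
#' @return list with `b0` and `sigma0` (micron). A non-dip fit (b0 <= 0)
#'   returns a zero-bleach profile.
#' @export
fit_bleach_profile <- function(post_bleach, pre_bleach, center, pixel_size,
                               fit_radius = 8) {
  stopifnot(all(dim(post_bleach) == dim(pre_bleach)))
  fs <- dim(post_bleach)
  x <- matrix(rep(0:(fs[2] - 1), each = fs[1]), fs[1], fs[2])
  y <- matrix(rep(0:(fs[1] - 1), times = fs[2]), fs[1], fs[2])
  r <- sqrt(((x - center[1]) * pixel_size)^2 +
              ((y - center[2]) * pixel_size)^2)
  keep <- r <= fit_radius & is.finite(post_bleach) & is.finite(pre_bleach) &
    pre_bleach > 0
  ratio <- post_bleach[keep] / pre_bleach[keep]
  rr <- r[keep]
  dip0 <- 1 - min(stats::ave(ratio, findInterval(rr, seq(0, fit_radius, 0.5)),
                             FUN = mean))
  if (!is.finite(dip0) || dip0 <= 0) return(list(b0 = 0, sigma0 = 1))
  df <- data.frame(ratio = ratio, rr = rr)
  fit <- try(minpack.lm::nlsLM(
    ratio ~ 1 - b0 * exp(-rr^2 / (2 * s0^2)), data = df,
    start = list(b0 = dip0, s0 = 1.5),
    lower = c(-0.5, 0.05), upper = c(1, fit_radius),
    control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
  if (inherits(fit, "try-error")) return(list(b0 = 0, sigma0 = 1))
  cf <- stats::coef(fit)
  if (cf[["b0"]] <= 0) return(list(b0 = 0, sigma0 = 1))
  list(b0 = unname(cf[["b0"]]), sigma0 = unname(cf[["s0"]]))
}

#' Fit the full diffusion model to a bleach-recovery image series
#'
#' Joint least squares of (b0, sigma0, D) over all frames of a recovery
#' series: each frame's intensity, normalized by the pre-bleach image, is
#' modeled as 1 - b(r, t) with the free-diffusion closed form.
#'
#' @param frames list of post-bleach intensity images.
#' @param times time since bleaching (s) of each frame.
#' @param pre_bleach pre-bleach intensity image.
#' @param center 0-based pixel c(x, y).
#' @param pixel_size micron per pixel.
#' @param fit_radius radius (micron) of pixels entering the fit.
#' @return list with `b0`, `sigma0` (micron), `D` (micron^2/s).
#' @export
fit_bleach_series <- function(frames, times, pre_bleach, center, pixel_size,
                              fit_radius = 8) {
  stopifnot(length(frames) == length(times))
  fs <- dim(pre_bleach)
  x <- matrix(rep(0:(fs[2] - 1), each = fs[1]), fs[1], fs[2])
  y <- matrix(rep(0:(fs[1] - 1), times = fs[2]), fs[1], fs[2])
  r <- sqrt(((x - center[1]) * pixel_size)^2 +
              ((y - center[2]) * pixel_size)^2)
  keep <- r <= fit_radius & is.finite(pre_bleach) & pre_bleach > 0
  obs <- unlist(lapply(frames, function(f) f[keep] / pre_bleach[keep]))
  rr <- rep(r[keep], times = length(frames))
  tt <- rep(times, each = sum(keep))
  init <- fit_bleach_profile(frames[[which.min(times)]], pre_bleach, center,
                             pixel_size, fit_radius)
  if (init$b0 <= 0) init <- list(b0 = 0.2, sigma0 = 1.5)
  df <- data.frame(obs = obs, rr = rr, tt = tt)
  fit <- minpack.lm::nlsLM(
    obs ~ 1 - b0 * s0^2 / (s0^2 + 2 * D * tt) *
      exp(-rr^2 / (2 * (s0^2 + 2 * D * tt))),
    data = df, start = list(b0 = init$b0, s0 = init$sigma0, D = 0.3),
    lower = c(0, 0.05, 0), upper = c(1, fit_radius, 50),
    control = minpack.lm::nls.lm.control(maxiter = 300))
  cf <- stats::coef(fit)
  list(b0 = unname(cf[["b0"]]), sigma0 = unname(cf[["s0"]]),
       D = unname(cf[["D"]]))
}

#' Simulate a focal-bleach recovery image series
#'
#' Renders a uniform sensor field with a Gaussian bleach dip spreading by
#' free diffusion, with Poisson shot noise, as acquired in a
#' high-power calibration measurement: one pre-bleach frame and a
#' post-bleach series.
#'
#' @param model `fret_bleach_model` (the generating truth).
#' @param times post-bleach sampling times (s).
#' @param field_shape c(rows, cols).
#' @param pixel_size micron per pixel.
#' @param level expected photon count of the unbleached field.
#' @param center 0-based c(x, y); defaults to the field center.
#' @param seed RNG seed for the shot noise.
#' @return list with `pre`, `frames` (list), `times`, `center`.
#' @export
simulate_frap_series <- function(model, times = seq(0.5, 10, by = 0.5),
                                 field_shape = c(64, 64),
                                 pixel_size = 0.325, level = 4000,
                                 center = NULL, seed = 1) {
  if (is.null(center))
    center <- c((field_shape[2] - 1) / 2, (field_shape[1] - 1) / 2)
  with_seed(seed, {
    pre <- matrix(stats::rpois(prod(field_shape), level),
                  field_shape[1], field_shape[2])
    frames <- lapply(times, function(t) {
      b <- propagate_bleach(model, t, field_shape, pixel_size,
                            center = center)
      matrix(stats::rpois(prod(field_shape), level * (1 - b)),
             field_shape[1], field_shape[2])
    })
    list(pre = pre, frames = frames, times = times, center = center)
  })
}

#' Correct a ratio-frame sequence for the bleached sensor pool
#'
#' For each post-stimulus frame the observed ratio is divided by
#' (1 - alpha * b(x, t - t_stim)), with contributions from multiple pulses
#' summed and clipped at b <= 1.
#'
#' @param frames list of `fret_ratio_frame` (see
#'   [compute_ratio_image()]) or plain ratio matrices.
#' @param model `fret_bleach_model`.
#' @param stim_log list of `fret_stimulus` (focal events carry target and
#'   power).
#' @param times frame times (s).
#' @param pixel_size micron per pixel.
#' @return list of corrected frames (same classes as input).
#' @export
correct_ratio_series <- function(frames, model, stim_log, times,
                                 pixel_size) {
  stopifnot(length(frames) == length(times))
  lapply(seq_along(frames), function(fr) {
    f <- frames[[fr]]
    ratio <- if (inherits(f, "fret_ratio_frame")) f$ratio else f
    fs <- dim(ratio)
    b <- matrix(0, fs[1], fs[2])
    for (s in stim_log) {
      if (s$kind != "focal" || s$time > times[fr]) next
      b <- b + propagate_bleach(model, times[fr] - s$time, fs, pixel_size,
                                center = s$target, power = s$power)
    }
    b <- pmin(b, 1)
    fac <- 1 - model$alpha * b
    if (any(fac <= 0))
      stop("bleach correction factor <= 0: mis-scaled bleach model")
    corrected <- ratio / fac
    if (inherits(f, "fret_ratio_frame")) {
      f$ratio <- corrected
      f
    } else corrected
  })
}

#' Persist / load a bleach model as JSON
#' @param model `fret_bleach_model`.
#' @param path file path.
#' @export
write_bleach_model <- function(model, path) {
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_bleach_model
#' @export
read_bleach_model <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  bleach_model(j$b0, j$sigma0, j$D, j$alpha, j$calibration_power,
               center = j$center)
}
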