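# Dual-camera channel registration.
#
# Simultaneously acquired donor/acceptor image pairs come from two cameras
# whose coordinate systems differ by translation, axis stretch, and mild
# second-order optical aberration. A 12-coefficient polynomial map from
# reference (acceptor) coordinates to donor coordinates is fitted by
# maximizing the Pearson correlation of gradient-feature images, then used
# to resample the donor channel onto acceptor coordinates so per-pixel
# ratios are geometrically valid.

#' Construct an alignment model
#'
#' The map operates on coordinates normalized per axis to [-1, 1]
#' (conditioning for the second-order terms). For each output axis the six
#' coefficients multiply (1, x, y, x^2, y^2, xy).
#'
#' @param coef_x,coef_y numeric length-6 coefficient vectors for the output
#'   x and y coordinate (normalized units).
#' @param ref_shape integer c(rows, cols) of the reference image.
#' @param fit_quality Pearson correlation achieved by the fit, if known.
#' @return an object of class `fret_alignment`.
#' @export
alignment_model <- function(coef_x = c(0, 1, 0, 0, 0, 0),
                            coef_y = c(0, 0, 1, 0, 0, 0),
                            ref_shape,
                            fit_quality = NA_real_) {
  stopifnot(length(coef_x) == 6, length(coef_y) == 6, length(ref_shape) == 2)
  m <- structure(
    list(coef_x = as.numeric(coef_x), coef_y = as.numeric(coef_y),
         ref_shape = as.integer(ref_shape), fit_quality = fit_quality),
    class = "fret_alignment")
  m
}

#' @export
print.fret_alignment <- function(x, ...) {
  cat("<fret_alignment> ref", paste(x$ref_shape, collapse = "x"),
      " fit_quality:", format(x$fit_quality, digits = 4), "\n")
  cat("  x':", format(x$coef_x, digits = 4), "\n")
  cat("  y':", format(x$coef_y, digits = 4), "\n")
  invisible(x)
}

.norm_coords <- function(x, n) 2 * x / (n - 1) - 1
.unnorm_coords <- function(xn, n) (xn + 1) * (n - 1) / 2

.poly_basis <- function(xn, yn) cbind(1, xn, yn, xn^2, yn^2, xn * yn)

#' Map reference coordinates through an alignment model
#'
#' @param model `fret_alignment`.
#' @param x,y 0-based pixel coordinates in the reference frame.
#' @return list with mapped `x`, `y` (0-based pixel coordinates in the
#'   donor frame).
#' @export
map_alignment <- function(model, x, y) {
  nr <- model$ref_shape[1]; nc <- model$ref_shape[2]
  B <- .poly_basis(.norm_coords(x, nc), .norm_coords(y, nr))
  list(x = .unnorm_coords(drop(B %*% model$coef_x), nc),
       y = .unnorm_coords(drop(B %*% model$coef_y), nr))
}

# Jacobian entries of the normalized map at normalized coords.
.map_jacobian <- function(model, xn, yn) {
  cx <- model$coef_x; cy <- model$coef_y
  list(
    dxdx = cx[2] + 2 * cx[4] * xn + cx[6] * yn,
    dxdy = cx[3] + 2 * cx[5] * yn + cx[6] * xn,
    dydx = cy[2] + 2 * cy[4] * xn + cy[6] * yn,
    dydy = cy[3] + 2 * cy[5] * yn + cy[6] * xn)
}

#' Check invertibility over the reference frame
#'
#' The Jacobian determinant of the normalized map must be positive at the
#' four corners and the center of the field.
#'
#' @param model `fret_alignment`.
#' @return logical scalar.
#' @export
alignment_invertible <- function(model) {
  pts <- rbind(c(-1, -1), c(-1, 1), c(1, -1), c(1, 1), c(0, 0))
  J <- .map_jacobian(model, pts[, 1], pts[, 2])
  all(J$dxdx * J$dydy - J$dxdy * J$dydx > 0)
}

#' Invert an alignment map at given donor coordinates
#'
#' Newton iteration in normalized coordinates; the fitted maps are small
#' perturbations of the identity so a handful of iterations converges to
#' machine precision.
#'
#' @param model `fret_alignment`.
#' @param x,y 0-based donor-frame coordinates.
#' @param iters Newton iterations.
#' @return list of reference-frame `x`, `y` (0-based).
#' @export
invert_alignment <- function(model, x, y, iters = 8L) {
  nr <- model$ref_shape[1]; nc <- model$ref_shape[2]
  qx <- .norm_coords(x, nc); qy <- .norm_coords(y, nr)
  px <- qx; py <- qy
  for (i in seq_len(iters)) {
    B <- .poly_basis(px, py)
    fx <- drop(B %*% model$coef_x) - qx
    fy <- drop(B %*% model$coef_y) - qy
    J <- .map_jacobian(model, px, py)
    det <- J$dxdx * J$dydy - J$dxdy * J$dydx
    px <- px - (J$dydy * fx - J$dxdy * fy) / det
    py <- py - (-J$dydx * fx + J$dxdx * fy) / det
  }
  list(x = .unnorm_coords(px, nc), y = .unnorm_coords(py, nr))
}

#' Prepare an image for correlation-based registration
#'
#' Background-subtracts at a low percentile floor, normalizes, smooths with
#' a Gaussian of radius 2, and takes the gradient magnitude to emphasize
#' object edges.
#'
#' @param img numeric matrix.
#' @param bg_percentile background floor percentile (fraction, default
#'   0.015).
#' @return feature matrix of the same shape. A constant input yields an
#'   all-zero feature image (flagged with attribute `flat = TRUE`).
#' @export
preprocess_for_alignment <- function(img, bg_percentile = 0.015) {
  stopifnot(all(is.finite(img)))
  bg <- finite_quantile(img, bg_percentile)
  img <- pmax(img - bg, 0)
  mx <- max(img)
  if (mx == 0) {
    out <- matrix(0, nrow(img), ncol(img))
    attr(out, "flat") <- TRUE
    return(out)
  }
  img <- img / mx
  s <- gauss_smooth(img, 2)
  gx <- matrix(0, nrow(s), ncol(s)); gy <- gx
  gx[, 2:(ncol(s) - 1)] <- (s[, 3:ncol(s)] - s[, 1:(ncol(s) - 2)]) / 2
  gy[2:(nrow(s) - 1), ] <- (s[3:nrow(s), ] - s[1:(nrow(s) - 2), ]) / 2
  sqrt(gx^2 + gy^2)
}

.bin_image <- function(img, f) {
  nr <- (nrow(img) %/% f) * f; nc <- (ncol(img) %/% f) * f
  img <- img[seq_len(nr), seq_len(nc)]
  a <- array(img, c(f, nr / f, f, nc / f))
  apply(a, c(2, 4), mean)
}

# Negative Pearson correlation between the reference feature image and the
# donor feature image warped through the candidate model. `ctx` carries a
# precomputed polynomial basis over the evaluation grid (a border margin of
# the reference is excluded: boundary padding of the feature transform is
# not warp-invariant and would bias the optimum) plus the reference values.
.align_objective <- function(par, ctx) {
  xm <- drop(ctx$B %*% par[1:6])
  ym <- drop(ctx$B %*% par[7:12])
  v <- bilinear_sample(ctx$fd, .unnorm_coords(xm, ctx$nc),
                       .unnorm_coords(ym, ctx$nr))
  ok <- !is.na(v)
  if (sum(ok) < 64) return(2)
  cc <- suppressWarnings(stats::cor(v[ok], ctx$fa_v[ok]))
  if (!is.finite(cc)) return(2)
  -cc
}

.align_ctx <- function(fd, fa, margin) {
  nr <- nrow(fa); nc <- ncol(fa)
  xs <- margin:(nc - 1 - margin); ys <- margin:(nr - 1 - margin)
  x <- rep(xs, each = length(ys)); y <- rep(ys, times = length(xs))
  list(B = .poly_basis(.norm_coords(x, nc), .norm_coords(y, nr)),
       fa_v = fa[cbind(y + 1, x + 1)], fd = fd, nr = nr, nc = nc)
}

.full_grid <- function(nr, nc) {
  list(x = rep(0:(nc - 1), each = nr), y = rep(0:(nr - 1), times = nc))
}

# Gauss-Newton refinement of the correlation objective. The simplex
# stages land in a long flat valley of the 12-parameter surface; this
# stage linearizes the warped feature image in the coefficients
# (sampling the gradient of fd at the mapped coordinates) and solves the
# damped normal equations for min_{a,s} ||fd(T(x)) - a - s*fa||, which
# shares its optimum with the Pearson correlation.
.align_polish <- function(par, ctx, iters = 10L) {
  gx <- matrix(0, ctx$nr, ctx$nc); gy <- gx
  fd <- ctx$fd
  gx[, 2:(ctx$nc - 1)] <- (fd[, 3:ctx$nc] - fd[, 1:(ctx$nc - 2)]) / 2
  gy[2:(ctx$nr - 1), ] <- (fd[3:ctx$nr, ] - fd[1:(ctx$nr - 2), ]) / 2
  sx <- (ctx$nc - 1) / 2; sy <- (ctx$nr - 1) / 2
  best <- par; best_val <- .align_objective(par, ctx)
  for (it in seq_len(iters)) {
    xm <- .unnorm_coords(drop(ctx$B %*% par[1:6]), ctx$nc)
    ym <- .unnorm_coords(drop(ctx$B %*% par[7:12]), ctx$nr)
    v <- bilinear_sample(fd, xm, ym)
    ok <- !is.na(v)
    if (sum(ok) < 200) break
    va <- v[ok]; fa <- ctx$fa_v[ok]
    ls <- stats::lm.fit(cbind(1, fa), va)
    r <- ls$residuals
    gxs <- bilinear_sample(gx, xm, ym)[ok]
    gys <- bilinear_sample(gy, xm, ym)[ok]
    B <- ctx$B[ok, , drop = FALSE]
    J <- cbind(B * (gxs * sx), B * (gys * sy))
    H <- crossprod(J)
    delta <- try(solve(H + 1e-8 * diag(diag(H)), crossprod(J, r)),
                 silent = TRUE)
    if (inherits(delta, "try-error")) break
    cand <- par - drop(delta)
    val <- .align_objective(cand, ctx)
    if (!is.finite(val) || val >= best_val - 1e-12) break
    par <- cand; best <- cand; best_val <- val
  }
  list(par = best, value = best_val)
}

#' Fit the donor-to-acceptor alignment model
#'
#' Staged derivative-free optimization of the Pearson correlation between
#' gradient-feature images: (1) translation only on 4x4-binned images,
#' (2) all 12 coefficients on the binned images, (3) all 12 coefficients on
#' the full-size feature images. Each stage warm-starts the next
#' (Nelder-Mead simplex with a polish restart).
#'
#' @param donor_ref,acceptor_ref reference images (e.g. sums of frames with
#'   cells across the field). Raw images; preprocessing is applied
#'   internally unless `preprocess = FALSE`.
#' @param cor_floor minimum acceptable final correlation (default 0.5);
#'   below it the registration is considered failed.
#' @param preprocess apply [preprocess_for_alignment()] (default TRUE).
#' @return `fret_alignment` with `fit_quality` set; attribute
#'   `stage_correlations` records the correlation after each stage.
#' @export
fit_alignment <- function(donor_ref, acceptor_ref, cor_floor = 0.5,
                          preprocess = TRUE) {
  stopifnot(all(dim(donor_ref) == dim(acceptor_ref)))
  fd <- if (preprocess) preprocess_for_alignment(donor_ref) else donor_ref
  fa <- if (preprocess) preprocess_for_alignment(acceptor_ref) else acceptor_ref
  if (sum(fd^2) == 0 || sum(fa^2) == 0)
    stop("reference images contain no structure (zero gradient energy)")
  nr <- nrow(fa); nc <- ncol(fa)
  id <- c(0, 1, 0, 0, 0, 0, 0, 0, 1, 0, 0, 0)

  bd <- .bin_image(fd, 4); ba <- .bin_image(fa, 4)
  ctx_b <- .align_ctx(bd, ba, margin = 4L)

  # stage 1: translation only, on binned images
  obj1 <- function(tr) .align_objective(replace(id, c(1, 7), tr), ctx_b)
  s1 <- stats::optim(c(0, 0), obj1, method = "Nelder-Mead",
                     control = list(maxit = 500, reltol = 1e-10,
                                    parscale = c(0.02, 0.02)))
  par <- replace(id, c(1, 7), s1$par)
  cor1 <- -s1$value

  # stage 2: all 12 parameters, binned
  ps <- c(0.02, 0.01, 0.002, 0.002, 0.002, 0.002)
  parscale <- c(ps, ps[c(1, 3, 2, 4, 5, 6)])
  s2 <- stats::optim(par, .align_objective, ctx = ctx_b,
                     method = "Nelder-Mead",
                     control = list(maxit = 3000, reltol = 1e-10,
                                    parscale = parscale))
  par <- s2$par
  cor2 <- -s2$value

  # stage 3: all 12 parameters at full resolution (short simplex), then a
  # Gauss-Newton polish of the same objective
  ctx <- .align_ctx(fd, fa, margin = 14L)
  s3 <- stats::optim(par, .align_objective, ctx = ctx,
                     method = "Nelder-Mead",
                     control = list(maxit = 600, reltol = 1e-8,
                                    parscale = parscale))
  pol <- .align_polish(s3$par, ctx)
  if (pol$value < s3$value) s3 <- pol
  cor3 <- -s3$value
  if (cor3 < cor_floor)
    stop(sprintf("registration failed: correlation %.3f below floor %.2f",
                 cor3, cor_floor))
  model <- alignment_model(s3$par[1:6], s3$par[7:12], c(nr, nc),
                           fit_quality = cor3)
  attr(model, "stage_correlations") <- c(stage1 = cor1, stage2 = cor2,
                                         stage3 = cor3)
  model
}

#' Resample a donor image onto acceptor coordinates
#'
#' Bilinear interpolation at the mapped coordinates; samples falling
#' outside the donor frame are returned as `NA` (invalid), never
#' extrapolated. An exact-identity model returns the input unchanged.
#'
#' @param img donor image matrix.
#' @param model `fret_alignment` with matching `ref_shape`.
#' @return aligned image matrix with `NA` at invalid pixels.
#' @export
apply_alignment <- function(img, model) {
  stopifnot(all(dim(img) == model$ref_shape))
  if (!alignment_invertible(model))
    stop("alignment model is not invertible over the reference frame")
  grid <- .full_grid(nrow(img), ncol(img))
  mapped <- map_alignment(model, grid$x, grid$y)
  matrix(bilinear_sample(img, mapped$x, mapped$y), nrow(img), ncol(img))
}

#' Persist / load an alignment model as JSON
#'
#' @param model `fret_alignment`.
#' @param path file path.
#' @return `write_alignment` returns `path` invisibly; `read_alignment`
#'   returns the model.
#' @export
write_alignment <- function(model, path) {
  jsonlite::write_json(
    list(coef_x = model$coef_x, coef_y = model$coef_y,
         ref_shape = model$ref_shape, fit_quality = model$fit_quality),
    path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_alignment
#' @export
read_alignment <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  alignment_model(j$coef_x, j$coef_y, j$ref_shape, j$fit_quality)
}
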