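# Low-level image helpers shared across the pipeline.
#
# Images are plain numeric matrices, row = y, column = x, origin at the
# top-left. Pixel centers sit at integer 0-based coordinates, so pixel
# [r, c] (1-based matrix indices) is at (x, y) = (c - 1, r - 1).

#' Separable Gaussian smoothing with reflective boundaries
#'
#' Smooths an image with an isotropic Gaussian kernel truncated at 3 sigma.
#' Reflective padding avoids the edge darkening that circular or zero
#' padding produce on correction fields.
#'
#' @param img numeric matrix.
#' @param sigma standard deviation in pixels; `sigma <= 0` returns the
#'   input unchanged.
#' @return smoothed matrix of the same shape.
#' @export
gauss_smooth <- function(img, sigma) {
  if (sigma <= 0) return(img)
  r <- ceiling(3 * sigma)
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  img <- .conv_axis(img, k, r, margin = 1L)
  .conv_axis(img, k, r, margin = 2L)
}

# 1-D convolution along rows (margin = 1) or columns (margin = 2) with
# mirror reflection at the borders (edge pixel not duplicated).
.conv_axis <- function(m, k, r, margin) {
  n <- dim(m)[margin]
  out <- matrix(0, nrow(m), ncol(m))
  for (j in -r:r) {
    idx <- seq_len(n) + j
    idx <- .reflect_index(idx, n)
    w <- k[j + r + 1L]
    if (margin == 1L) out <- out + w * m[idx, , drop = FALSE]
    else out <- out + w * m[, idx, drop = FALSE]
  }
  out
}

.reflect_index <- function(idx, n) {
  if (n == 1L) return(rep(1L, length(idx)))
  # mirror about 1 and n until all indices fall inside [1, n]
  while (any(idx < 1L) || any(idx > n)) {
    idx <- ifelse(idx < 1L, 2L - idx, idx)
    idx <- ifelse(idx > n, 2L * n - idx, idx)
  }
  idx
}

#' Bilinear sampling at fractional pixel coordinates
#'
#' Samples `img` at 0-based coordinates (`x` = column, `y` = row) by
#' bilinear interpolation. Coordinates outside the image domain return
#' `NA` (values are never extrapolated). Coordinates within 1e-9 of an
#' integer grid point return the stored pixel value exactly.
#'
#' @param img numeric matrix.
#' @param x,y numeric vectors of equal length, 0-based.
#' @return numeric vector of sampled values.
#' @export
bilinear_sample <- function(img, x, y) {
  nr <- nrow(img); nc <- ncol(img)
  # snap near-integer coordinates so identity maps are bit-exact
  xs <- round(x); ys <- round(y)
  x <- ifelse(abs(x - xs) < 1e-9, xs, x)
  y <- ifelse(abs(y - ys) < 1e-9, ys, y)
  ok <- x >= 0 & x <= nc - 1 & y >= 0 & y <= nr - 1 & is.finite(x) & is.finite(y)
  out <- rep(NA_real_, length(x))
  if (!any(ok)) return(out)
  x <- x[ok]; y <- y[ok]
  x0 <- pmin(floor(x), nc - 2); y0 <- pmin(floor(y), nr - 2)
  x0 <- pmax(x0, 0); y0 <- pmax(y0, 0)
  fx <- x - x0; fy <- y - y0
  i00 <- (x0) * nr + y0 + 1
  v <- (1 - fx) * (1 - fy) * img[i00] +
    fx * (1 - fy) * img[i00 + nr] +
    (1 - fx) * fy * img[i00 + 1] +
    fx * fy * img[i00 + nr + 1]
  out[ok] <- v
  out
}

#' 8-connected component labeling
#'
#' Labels connected foreground regions of a logical mask using
#' 8-connectivity (edge and corner neighbors), as used for cell masks.
#'
#' @param mask logical matrix; `TRUE`/nonzero is foreground.
#' @return integer matrix of labels, background = 0, labels 1..n compact.
#' @export
label_components <- function(mask) {
  mask <- mask != 0
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0, nr, nc)
  lab[mask] <- seq_len(sum(mask))
  if (all(lab == 0)) return(matrix(0L, nr, nc))
  shifts <- list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1),
                 c(1, 1), c(1, -1), c(-1, 1), c(-1, -1))
  big <- .Machine$integer.max
  repeat {
    new <- lab
    for (s in shifts) {
      shifted <- matrix(big, nr, nc)
      rs <- s[1]; cs <- s[2]
      r_dst <- max(1, 1 + rs):min(nr, nr + rs)
      c_dst <- max(1, 1 + cs):min(nc, nc + cs)
      shifted[r_dst, c_dst] <- lab[r_dst - rs, c_dst - cs]
      shifted[shifted == 0] <- big
      new <- pmin(new, ifelse(mask & new > 0, shifted, new))
    }
    new[!mask] <- 0
    if (identical(new, lab)) break
    lab <- new
  }
  u <- sort(unique(lab[lab > 0]))
  out <- matrix(0L, nr, nc)
  out[lab > 0] <- match(lab[lab > 0], u)
  out
}

#' Otsu threshold of an image
#'
#' Thin wrapper around \code{EBImage::otsu} operating on an arbitrary-range
#' matrix.
#'
#' @param img numeric matrix.
#' @return scalar threshold on the scale of `img`.
#' @export
otsu_threshold <- function(img) {
  rng <- range(img, finite = TRUE)
  if (diff(rng) == 0) return(rng[1])
  EBImage::otsu(EBImage::Image(img), range = rng, levels = 256L)
}

# Quantile with linear interpolation, ignoring non-finite values.
finite_quantile <- function(x, p) {
  stats::quantile(x[is.finite(x)], p, names = FALSE, type = 7)
}

# Evaluate a scoped expression with a temporary RNG state seeded from
# `seed`, restoring the caller's state afterwards. Keeps all generator
# randomness reproducible without clobbering the session RNG.
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(expr)
}

# Deterministic per-stream sub-seed derived from a master seed, so each
# cell / frame / channel consumes an order-independent random stream.
derive_seed <- function(seed, ...) {
  parts <- c(seed, ...)
  h <- 0
  for (p in parts) h <- (h * 1000003 + as.numeric(p) + 12345) %% 2147483629
  as.integer(h)
}
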