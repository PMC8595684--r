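# Shared fixtures: analytic blob fields, disk masks, and polynomial warp
# construction in pixel units (converted to the normalized-coordinate
# convention of alignment_model).

make_blobs <- function(n = 14, seed = 1, fs = c(160, 160), offset = 100) {
  set.seed(seed)
  list(df = data.frame(cx = runif(n, 14, fs[2] - 14),
                       cy = runif(n, 14, fs[1] - 14),
                       s = runif(n, 4, 9), a = runif(n, 500, 2000)),
       offset = offset, fs = fs)
}

eval_blobs <- function(b, x, y) {
  v <- rep(b$offset, length(x))
  for (i in seq_len(nrow(b$df)))
    v <- v + b$df$a[i] *
      exp(-((x - b$df$cx[i])^2 + (y - b$df$cy[i])^2) / (2 * b$df$s[i]^2))
  v
}

blob_image <- function(b) {
  g <- full_grid_xy(b$fs)
  matrix(eval_blobs(b, g$x, g$y), b$fs[1], b$fs[2])
}

full_grid_xy <- function(fs) {
  list(x = rep(0:(fs[2] - 1), each = fs[1]),
       y = rep(0:(fs[1] - 1), times = fs[2]))
}

# pixel-space polynomial warp -> alignment_model (normalized coefficients)
pixel_warp_model <- function(fs, tx = 0, ty = 0, stx = 1, sty = 1,
                             q = rep(0, 6)) {
  sx <- (fs[2] - 1) / 2; sy <- (fs[1] - 1) / 2
  cx <- c((tx + stx * sx + q[1] * sx^2 + q[2] * sy^2 + q[3] * sx * sy) / sx - 1,
          (stx * sx + 2 * q[1] * sx^2 + q[3] * sx * sy) / sx,
          (2 * q[2] * sy^2 + q[3] * sx * sy) / sx,
          q[1] * sx^2 / sx, q[2] * sy^2 / sx, q[3] * sx * sy / sx)
  cy <- c((ty + sty * sy + q[4] * sy^2 + q[5] * sx^2 + q[6] * sx * sy) / sy - 1,
          (2 * q[5] * sx^2 + q[6] * sx * sy) / sy,
          (sty * sy + 2 * q[4] * sy^2 + q[6] * sx * sy) / sy,
          q[4] * sy^2 / sy, q[5] * sx^2 / sy, q[6] * sx * sy / sy)
  alignment_model(cx, cy, fs)
}

random_warp_model <- function(fs, seed, max_shift = 10, max_stretch = 0.01,
                              max_q = 1e-5) {
  set.seed(seed)
  pixel_warp_model(fs,
                   tx = runif(1, -max_shift, max_shift),
                   ty = runif(1, -max_shift, max_shift),
                   stx = 1 + runif(1, -max_stretch, max_stretch),
                   sty = 1 + runif(1, -max_stretch, max_stretch),
                   q = runif(6, -max_q, max_q))
}

# render a donor image analytically through the inverse of a true warp
warp_blob_image <- function(b, model) {
  g <- full_grid_xy(b$fs)
  inv <- invert_alignment(model, g$x, g$y)
  matrix(eval_blobs(b, inv$x, inv$y), b$fs[1], b$fs[2])
}

rms_map_error <- function(m1, m2, fs) {
  g <- full_grid_xy(fs)
  a <- map_alignment(m1, g$x, g$y); b <- map_alignment(m2, g$x, g$y)
  sqrt(mean((a$x - b$x)^2 + (a$y - b$y)^2))
}

disk_mask <- function(fs, cx, cy, r) {
  x <- matrix(rep(0:(fs[2] - 1), each = fs[1]), fs[1], fs[2])
  y <- matrix(rep(0:(fs[1] - 1), times = fs[2]), fs[1], fs[2])
  (x - cx)^2 + (y - cy)^2 <= r^2
}
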