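# Camera and illumination corrections.
#
# Four corrections remove systematic camera/illumination artifacts before
# ratio computation:
#   * dark image   -- per-pixel median of unilluminated frames, subtracted;
#   * half-chip    -- multiplicative step correcting the sensitivity
#                    difference between the two halves of a camera chip;
#   * dust         -- multiplicative field restoring a dim dust spot to the
#                    value of the smooth illumination field;
#   * ratio        -- multiplicative field (mean 1) dividing out the
#                    systematic top-to-bottom gradient in ratio images.
# Dark/half-chip/dust apply to raw channel frames; the ratio correction
# applies to ratio images downstream.

#' Build a dark-state correction image
#'
#' @param dark_frames list of >= 2 unilluminated frames (matrices of one
#'   shape).
#' @return per-pixel median image (counts); applied by subtraction with
#'   clipping at 0.
#' @export
build_dark_correction <- function(dark_frames) {
  if (length(dark_frames) < 2)
    stop("insufficient calibration: need at least 2 dark frames")
  d <- dim(dark_frames[[1]])
  if (!all(vapply(dark_frames, function(f) all(dim(f) == d), TRUE)))
    stop("dark frames must share one shape")
  a <- array(unlist(dark_frames), c(d, length(dark_frames)))
  apply(a, c(1, 2), stats::median)
}

#' Build a half-chip sensitivity correction
#'
#' The two camera-chip halves can differ in sensitivity. The correction
#' factor is the ratio of the mean intensity of the two rows just above
#' the chip middle to the two rows just below it, measured on a median
#' uniform-dye image; the returned field is 1 on the top half and the
#' factor on the bottom half, applied by multiplication.
#'
#' @param dye_median median uniform-dye image (dark-subtracted).
#' @param mid_row middle row (1-based count of top-half rows); defaults to
#'   rows/2.
#' @return list with `field` (matrix) and `factor` (scalar).
#' @export
build_half_chip_correction <- function(dye_median,
                                       mid_row = nrow(dye_median) %/% 2) {
  if (nrow(dye_median) < 4) stop("image must have at least 4 rows")
  above <- mean(dye_median[(mid_row - 1):mid_row, ])
  below <- mean(dye_median[(mid_row + 1):(mid_row + 2), ])
  if (below == 0 || above == 0)
    stop("invalid dye image: zero mean in reference rows")
  factor <- above / below
  field <- matrix(1, nrow(dye_median), ncol(dye_median))
  field[(mid_row + 1):nrow(field), ] <- factor
  list(field = field, factor = factor)
}

#' Build a dust-spot correction field
#'
#' The dye image is divided by a broad Gaussian smoothing of itself
#' (sigma 30); pixels falling below `dim_threshold` of the smooth field
#' are flagged as the dust spot. The flagged mask is feathered with a
#' sigma-10 Gaussian and used to blend the image toward the smooth field,
#' yielding a multiplicative field that restores flagged pixels to their
#' smooth-field value and leaves pixels outside the feathered spot at
#' exactly 1.
#'
#' @param dye_median strictly positive median dye image (half-chip
#'   corrected).
#' @param smooth_sigma broad smoothing sigma (px, default 30).
#' @param spot_sigma mask feathering sigma (px, default 10).
#' @param dim_threshold flag pixels with dye/smooth below this fraction
#'   (default 0.98, i.e. >= 2% dimmer than the smooth field).
#' @return multiplicative dust-correction matrix.
#' @export
build_dust_correction <- function(dye_median, smooth_sigma = 30,
                                  spot_sigma = 10, dim_threshold = 0.98) {
  if (any(dye_median <= 0)) stop("dye image must be strictly positive")
  smooth <- gauss_smooth(dye_median, smooth_sigma)
  rel <- dye_median / smooth
  flagged <- rel < dim_threshold
  if (mean(flagged) > 0.10)
    stop(sprintf("bad calibration image: %.1f%% of pixels flagged as dust",
                 100 * mean(flagged)))
  if (!any(flagged))
    return(matrix(1, nrow(dye_median), ncol(dye_median)))
  # second pass: the broad smoothing itself is depressed by the spot, so
  # re-estimate the artifact-free field with the flagged region inpainted
  repaired <- dye_median
  repaired[flagged] <- smooth[flagged]
  smooth <- gauss_smooth(repaired, smooth_sigma)
  w <- gauss_smooth(flagged * 1, spot_sigma)
  w <- pmin(w / max(w), 1)
  w[flagged] <- 1   # flagged pixels fully restored; feather only outside
  1 + w * (smooth / dye_median - 1)
}

#' Build the ratio-correction image
#'
#' Captures the systematic spatial gradient of ratio images: per-pixel
#' median of in-mask ratios over a stack of unstimulated cells, block
#' medians over `block` x `block` tiles (partial tiles at borders; empty
#' tiles filled from neighbors), Gaussian smoothing (sigma in block
#' units), bilinear upsampling to full size, and rescaling to mean 1 so
#' absolute ratio levels are preserved. Applied by dividing ratio images.
#'
#' @param ratio_images list of ratio matrices.
#' @param cell_masks list of logical matrices (same shapes).
#' @param block tile size in pixels (default 24).
#' @param smooth_sigma Gaussian sigma in block units (default 5).
#' @return ratio-correction matrix with mean 1.
#' @export
build_ratio_correction <- function(ratio_images, cell_masks, block = 24,
                                   smooth_sigma = 5) {
  if (length(ratio_images) == 0 || !any(unlist(lapply(cell_masks, any))))
    stop("no calibration cells: empty mask stack")
  d <- dim(ratio_images[[1]])
  acc <- array(NA_real_, c(d, length(ratio_images)))
  for (i in seq_along(ratio_images)) {
    m <- ratio_images[[i]]
    m[!cell_masks[[i]]] <- NA
    acc[, , i] <- m
  }
  px_med <- apply(acc, c(1, 2), function(v)
    if (all(is.na(v))) NA_real_ else stats::median(v, na.rm = TRUE))
  nbr <- ceiling(d[1] / block); nbc <- ceiling(d[2] / block)
  bm <- matrix(NA_real_, nbr, nbc)
  for (i in seq_len(nbr)) for (j in seq_len(nbc)) {
    rows <- ((i - 1) * block + 1):min(i * block, d[1])
    cols <- ((j - 1) * block + 1):min(j * block, d[2])
    v <- px_med[rows, cols]
    if (any(is.finite(v))) bm[i, j] <- stats::median(v, na.rm = TRUE)
  }
  bm <- .fill_blocks(bm)
  # smooth while preserving the large-scale gradient the correction must
  # capture: remove the best-fit plane (reflective smoothing would flatten
  # it near the borders), smooth the residual, restore the plane
  ri <- row(bm); ci <- col(bm)
  pl <- stats::lm.fit(cbind(1, as.vector(ri), as.vector(ci)), as.vector(bm))
  plane <- matrix(pl$fitted.values, nrow(bm), ncol(bm))
  bm <- plane + gauss_smooth(bm - plane, smooth_sigma)
  # bilinear upsample from block centers, extrapolating linearly beyond the
  # outermost centers (one padded ring) so border pixels are corrected too
  pad_lin <- function(m) {
    m <- rbind(2 * m[1, ] - m[2, ], m, 2 * m[nrow(m), ] - m[nrow(m) - 1, ])
    cbind(2 * m[, 1] - m[, 2], m, 2 * m[, ncol(m)] - m[, ncol(m) - 1])
  }
  bmp <- pad_lin(bm)
  bx <- ((seq_len(nbc) - 1) * block + pmin(seq_len(nbc) * block, d[2]) - 1) / 2
  by <- ((seq_len(nbr) - 1) * block + pmin(seq_len(nbr) * block, d[1]) - 1) / 2
  bx <- c(2 * bx[1] - bx[2], bx, 2 * bx[nbc] - bx[nbc - 1])
  by <- c(2 * by[1] - by[2], by, 2 * by[nbr] - by[nbr - 1])
  fx <- stats::approx(bx, seq_along(bx), xout = 0:(d[2] - 1), rule = 2)$y
  fy <- stats::approx(by, seq_along(by), xout = 0:(d[1] - 1), rule = 2)$y
  grid_x <- rep(fx - 1, each = d[1])
  grid_y <- rep(fy - 1, times = d[2])
  up <- matrix(bilinear_sample(bmp, grid_x, grid_y), d[1], d[2])
  up / mean(up)
}

# Fill NA blocks by iterative neighbor averaging (4-neighborhood).
.fill_blocks <- function(bm) {
  while (any(is.na(bm))) {
    nas <- which(is.na(bm), arr.ind = TRUE)
    filled_any <- FALSE
    for (k in seq_len(nrow(nas))) {
      i <- nas[k, 1]; j <- nas[k, 2]
      nb <- c(if (i > 1) bm[i - 1, j], if (i < nrow(bm)) bm[i + 1, j],
              if (j > 1) bm[i, j - 1], if (j < ncol(bm)) bm[i, j + 1])
      if (any(is.finite(nb))) {
        bm[i, j] <- mean(nb, na.rm = TRUE)
        filled_any <- TRUE
      }
    }
    if (!filled_any) { bm[is.na(bm)] <- 1; break }
  }
  bm
}

#' Assemble a correction set
#'
#' @param dark_donor,dark_acceptor dark images per camera.
#' @param half_chip_donor,half_chip_acceptor half-chip fields (default
#'   unit fields).
#' @param dust_donor,dust_acceptor dust-correction fields (default unit).
#' @param ratio_correction ratio-correction field (default unit).
#' @param provenance optional list of calibration frame counts.
#' @return list of class `fret_corrections`.
#' @export
correction_set <- function(dark_donor, dark_acceptor,
                           half_chip_donor = NULL, half_chip_acceptor = NULL,
                           dust_donor = NULL, dust_acceptor = NULL,
                           ratio_correction = NULL, provenance = list()) {
  d <- dim(dark_donor)
  unit <- matrix(1, d[1], d[2])
  cs <- list(
    dark = list(donor = dark_donor, acceptor = dark_acceptor),
    half_chip = list(donor = half_chip_donor %||% unit,
                     acceptor = half_chip_acceptor %||% unit),
    dust = list(donor = dust_donor %||% unit,
                acceptor = dust_acceptor %||% unit),
    ratio_correction = ratio_correction %||% unit,
    provenance = provenance)
  for (f in c(cs$half_chip, cs$dust, list(cs$ratio_correction)))
    if (any(!is.finite(f)) || any(f <= 0))
      stop("multiplicative correction fields must be strictly positive and finite")
  if (any(cs$dark$donor < 0) || any(cs$dark$acceptor < 0))
    stop("dark images must be non-negative")
  class(cs) <- "fret_corrections"
  cs
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Identity correction set (zero dark, unit fields)
#' @param field_shape c(rows, cols).
#' @return `fret_corrections`.
#' @export
identity_corrections <- function(field_shape) {
  z <- matrix(0, field_shape[1], field_shape[2])
  correction_set(z, z)
}

#' Apply channel corrections to a raw frame
#'
#' Order: dark subtraction (clipped at 0), then half-chip multiplication,
#' then dust multiplication. The ratio correction is not applied here; it
#' divides ratio images downstream.
#'
#' @param frame raw image matrix.
#' @param camera "donor" or "acceptor".
#' @param corrections `fret_corrections`.
#' @return corrected image matrix.
#' @export
apply_corrections <- function(frame, camera = c("donor", "acceptor"),
                              corrections) {
  camera <- match.arg(camera)
  if (!all(dim(frame) == dim(corrections$dark[[camera]])))
    stop("frame shape does not match correction images")
  out <- pmax(frame - corrections$dark[[camera]], 0)
  out * corrections$half_chip[[camera]] * corrections$dust[[camera]]
}

#' Build a full correction set from calibration stacks
#'
#' Convenience wrapper running all builders: dark medians per camera,
#' half-chip and dust corrections from median dye images, and (optionally)
#' the ratio correction from unstimulated-cell ratio images.
#'
#' @param dark_frames list with `donor`, `acceptor` lists of dark frames.
#' @param dye_frames list with `donor`, `acceptor` lists of dye frames.
#' @param ratio_images,cell_masks optional stacks for the ratio
#'   correction.
#' @param dim_threshold dust flagging threshold.
#' @return `fret_corrections`.
#' @export
build_correction_set <- function(dark_frames, dye_frames,
                                 ratio_images = NULL, cell_masks = NULL,
                                 dim_threshold = 0.98) {
  dk_d <- build_dark_correction(dark_frames$donor)
  dk_a <- build_dark_correction(dark_frames$acceptor)
  med_dye <- function(frames, dark) {
    a <- array(unlist(frames), c(dim(dark), length(frames)))
    pmax(apply(a, c(1, 2), stats::median) - dark, 1e-6)
  }
  dye_d <- med_dye(dye_frames$donor, dk_d)
  dye_a <- med_dye(dye_frames$acceptor, dk_a)
  hc_d <- build_half_chip_correction(dye_d)
  hc_a <- build_half_chip_correction(dye_a)
  dust_d <- build_dust_correction(dye_d * hc_d$field,
                                  dim_threshold = dim_threshold)
  dust_a <- build_dust_correction(dye_a * hc_a$field,
                                  dim_threshold = dim_threshold)
  rc <- if (!is.null(ratio_images))
    build_ratio_correction(ratio_images, cell_masks) else NULL
  correction_set(dk_d, dk_a, hc_d$field, hc_a$field, dust_d, dust_a, rc,
                 provenance = list(n_dark = length(dark_frames$donor),
                                   n_dye = length(dye_frames$donor)))
}
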