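#' Gaussian point spread function kernel
#'
#' Builds a normalized 2D Gaussian kernel whose full width at half maximum
#' equals the optical PSF diameter expressed in pixels. The widefield default
#' follows the Abbe limit `0.61 * lambda / NA`: with GCaMP emission
#' `lambda = 0.51` um and a 0.28 NA objective this gives 1.1 um.
#'
#' @param diameter_um PSF diameter (FWHM) in micrometres (default 1.1).
#' @param pixel_size Pixel size in um/pixel (default 2.9).
#' @return A square numeric matrix summing to 1. If the FWHM is below one
#'   pixel a warning notes that the kernel is close to a delta.
#' @export
gaussian_psf <- function(diameter_um = 1.1, pixel_size = 2.9) {
  check_positive(diameter_um, "diameter_um")
  check_positive(pixel_size, "pixel_size")
  fwhm_px <- diameter_um / pixel_size
  if (fwhm_px < 1)
    warning(sprintf("PSF FWHM %.2f px is below one pixel; kernel is near-delta",
                    fwhm_px))
  sigma <- fwhm_px / (2 * sqrt(2 * log(2)))
  r <- max(1L, ceiling(3 * sigma))
  g <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k <- outer(g, g)
  k / sum(k)
}

#' Abbe-limit PSF diameter
#'
#' `0.61 * lambda / NA`: the diffraction-limited resolution used as the PSF
#' diameter for widefield deconvolution. The defaults (GCaMP emission at
#' 0.51 um through a 0.28 NA objective) give 1.1 um.
#'
#' @param lambda_um Emission wavelength in micrometres.
#' @param na Numerical aperture of the objective.
#' @return PSF diameter in micrometres.
#' @export
abbe_psf_diameter <- function(lambda_um = 0.51, na = 0.28) {
  check_positive(lambda_um, "lambda_um")
  check_positive(na, "na")
  0.61 * lambda_um / na
}

# Frame-wise 2D convolution with replicated edges. Small kernels run in
# compiled code (memory-light); larger ones use the EBImage FFT backend.
conv_frames <- function(arr, kernel) {
  if (max(dim(kernel)) <= 15) conv_small(arr, kernel)
  else EBImage::filter2(arr, kernel, boundary = "replicate")
}

conv_small <- function(arr, kernel) {
  d <- dim(arr)
  two_d <- length(d) == 2L
  if (two_d) d <- c(d, 1L)
  out <- cpp_conv2_frames(as.numeric(arr), as.integer(d), kernel)
  if (two_d) matrix(out, d[1], d[2]) else array(out, d)
}

#' Richardson-Lucy deconvolution
#'
#' Frame-wise iterative Richardson-Lucy deconvolution with a fixed iteration
#' count. Before iterating, each frame border is tapered toward its
#' PSF-smoothed version over a band two PSF widths wide, which suppresses the
#' ringing artifacts that iterative deconvolution otherwise generates at hard
#' image edges.
#'
#' @param stack A [timelapse_stack()] or 3D array.
#' @param psf Normalized PSF kernel, e.g. from [gaussian_psf()].
#' @param iterations Number of RL iterations (default 10, which smooths
#'   out-of-focus blur without amplifying noise).
#' @return A `corrected_stack`: list with the deconvolved nonnegative `data`
#'   array and the parameters used.
#' @export
deconvolve <- function(stack, psf, iterations = 10) {
  check_count(iterations, "iterations", min = 1L)
  if (abs(sum(psf) - 1) > 1e-6)
    stop("`psf` must be normalized (sum to 1)", call. = FALSE)
  arr <- if (inherits(stack, "timelapse_stack")) stack$data else stack
  if (is.matrix(arr)) arr <- array(arr, c(dim(arr), 1L))
  d <- dim(arr)
  # edge taper: blend border band toward the smoothed image
  fwhm_px <- max(1, (ncol(psf) - 1) / 6 * (2 * sqrt(2 * log(2))))
  band <- max(2L, ceiling(2 * fwhm_px))
  wr <- clamp((pmin(seq_len(d[1]) - 1, d[1] - seq_len(d[1]))) / band, 0, 1)
  wc <- clamp((pmin(seq_len(d[2]) - 1, d[2] - seq_len(d[2]))) / band, 0, 1)
  w <- as.vector(outer(wr, wc, pmin))
  psf_m <- psf[nrow(psf):1, ncol(psf):1, drop = FALSE]   # mirrored PSF
  eps <- 1e-12
  out <- array(0, d)
  # frames are independent: iterate in chunks to bound peak memory
  chunk <- max(1L, min(d[3], as.integer(2^25 / (d[1] * d[2]))))
  for (c0 in seq(1L, d[3], by = chunk)) {
    c1 <- min(d[3], c0 + chunk - 1L)
    sub <- arr[, , c0:c1, drop = FALSE]
    obs <- pmax(sub * w + conv_frames(sub, psf) * (1 - w), 0)
    est <- obs
    for (i in seq_len(iterations)) {
      ratio <- obs / (conv_frames(est, psf) + eps)
      est <- est * conv_frames(ratio, psf_m)
    }
    out[, , c0:c1] <- pmax(est, 0)
  }
  structure(list(data = out, psf = psf, iterations = iterations),
            class = "corrected_stack")
}

#' Morphological background field of a single frame
#'
#' Grayscale opening with a flat disk structuring element. Bright structures
#' narrower than the disk are removed while smooth background (including
#' linear gradients, for which opening is exact away from the border) is
#' preserved, yielding a per-frame background estimate. Opening is
#' anti-extensive, so the field never exceeds the frame.
#'
#' @param frame 2D numeric matrix.
#' @param opening_radius_px Disk radius in pixels (default 15).
#' @return The background image (same size).
#' @export
background_field <- function(frame, opening_radius_px = 15) {
  check_count(opening_radius_px, "opening_radius_px", min = 1L)
  brush <- EBImage::makeBrush(2L * as.integer(opening_radius_px) + 1L, "disc")
  # EBImage grayscale morphology operates on [0, 1]; opening commutes with
  # positive affine maps, so rescale around the call
  lo <- min(frame); hi <- max(frame)
  if (hi <= lo) return(frame + 0)
  opened <- EBImage::opening((frame - lo) / (hi - lo), brush)
  matrix(opened, nrow(frame), ncol(frame)) * (hi - lo) + lo
}

#' Background-correct a deconvolved stack
#'
#' For each frame, the colony pixels are blanked, a smooth background field is
#' estimated from the remaining (non-colony) image by [background_field()],
#' and that field is subtracted; negative results are clipped to zero.
#'
#' @param corrected A `corrected_stack` (from [deconvolve()]) or 3D array.
#' @param mask A `colony_mask` or logical matrix of colony pixels.
#' @param opening_radius_px Disk radius for the background opening.
#' @return A `corrected_stack` with background removed.
#' @export
subtract_background_field <- function(corrected, mask, opening_radius_px = 15) {
  arr <- if (inherits(corrected, "corrected_stack")) corrected$data else corrected
  m <- if (inherits(mask, "colony_mask")) mask$mask else mask
  d <- dim(arr)
  out <- arr
  for (i in seq_len(d[3])) {
    fr <- arr[, , i]
    fr[m] <- 0
    bg <- background_field(fr, opening_radius_px)
    out[, , i] <- pmax(arr[, , i] - bg, 0)
  }
  structure(list(data = out,
                 psf = if (inherits(corrected, "corrected_stack")) corrected$psf else NULL,
                 iterations = if (inherits(corrected, "corrected_stack")) corrected$iterations else NULL,
                 opening_radius_px = opening_radius_px),
            class = "corrected_stack")
}

#' Deconvolve and background-correct a stack in one pass
#'
#' Runs [deconvolve()] and [subtract_background_field()] over frame chunks,
#' so only one full-size output array is ever held in memory. This is the
#' normalization stage the pipeline uses.
#'
#' @param stack A [timelapse_stack()] or 3D array.
#' @param mask A `colony_mask` or logical matrix.
#' @param psf_diameter_um PSF FWHM in micrometres.
#' @param iterations Richardson-Lucy iterations.
#' @param opening_radius_px Background-field opening radius (px).
#' @return A `corrected_stack`.
#' @export
normalize_stack <- function(stack, mask, psf_diameter_um = 1.1,
                            iterations = 10, opening_radius_px = 15) {
  arr <- arr_3d(stack)
  px <- if (inherits(stack, "timelapse_stack")) stack$pixel_size else 2.9
  m <- if (inherits(mask, "colony_mask")) mask$mask else mask
  psf <- suppressWarnings(gaussian_psf(psf_diameter_um, px))
  d <- dim(arr)
  out <- array(0, d)
  chunk <- max(1L, min(d[3], as.integer(2^23 / (d[1] * d[2]))))
  for (c0 in seq(1L, d[3], by = chunk)) {
    c1 <- min(d[3], c0 + chunk - 1L)
    dec <- deconvolve(arr[, , c0:c1, drop = FALSE], psf, iterations)
    sub <- subtract_background_field(dec, m, opening_radius_px)
    out[, , c0:c1] <- sub$data
  }
  structure(list(data = out, psf = psf, iterations = iterations,
                 opening_radius_px = opening_radius_px),
            class = "corrected_stack")
}

#' Per-pixel Z-score normalization over time
#'
#' For every colony pixel, subtracts the temporal mean and divides by the
#' temporal standard deviation (sample SD, n-1 denominator), making pixel
#' dynamics comparable irrespective of time-averaged intensity: pixels with
#' identical dynamics at different brightness get identical Z-traces, and the
#' transform is exactly invariant to per-pixel affine intensity maps
#' `a*x + b` with `a > 0`. Pixels with zero temporal SD map to all-zero
#' Z-traces (they join a flat cluster and are pruned downstream).
#'
#' @param corrected A `corrected_stack` or 3D array (m x n x t, t >= 2).
#' @param mask A `colony_mask` or logical matrix selecting colony pixels.
#' @return A `pixel_matrix`: list with `z` (foreground pixels x time matrix of
#'   Z-scores), `coords` (matrix of 1-based `(row, col)` per matrix row), and
#'   `dim` (frame size). This is the flattened pixels-by-time representation
#'   consumed by clustering.
#' @export
zscore_pixels <- function(corrected, mask) {
  arr <- if (inherits(corrected, "corrected_stack")) corrected$data else arr_3d(corrected)
  m <- if (inherits(mask, "colony_mask")) mask$mask else mask
  d <- dim(arr)
  if (d[3] < 2) stop("Z-scores over time need at least 2 frames", call. = FALSE)
  idx <- which(m)
  flat <- matrix(arr, d[1] * d[2], d[3])[idx, , drop = FALSE]
  mu <- rowMeans(flat)
  cen <- flat - mu
  sdv <- sqrt(rowSums(cen^2) / (d[3] - 1))
  z <- cen / ifelse(sdv > 0, sdv, 1)
  z[sdv == 0, ] <- 0
  coords <- cbind(row = ((idx - 1) %% d[1]) + 1L,
                  col = ((idx - 1) %/% d[1]) + 1L)
  structure(list(z = z, coords = coords, dim = d[1:2]),
            class = "pixel_matrix")
}

arr_3d <- function(x) {
  if (inherits(x, "timelapse_stack")) return(x$data)
  if (is.matrix(x)) return(array(x, c(dim(x), 1L)))
  x
}

#' @export
print.pixel_matrix <- function(x, ...) {
  cat(sprintf("<pixel_matrix> %d foreground px x %d time points (%d x %d frame)\n",
              nrow(x$z), ncol(x$z), x$dim[1], x$dim[2]))
  invisible(x)
}
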