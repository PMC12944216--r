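#' Maximum-intensity z-projection
#'
#' Flattens a timelapse to a single image in which every pixel holds its
#' maximum over all frames, so that any region that lights up at some point
#' during the recording appears bright.
#'
#' @param stack A [timelapse_stack()] or 3D array.
#' @return A 2D numeric matrix.
#' @export
max_project <- function(stack) {
  arr <- if (inherits(stack, "timelapse_stack")) stack$data else stack
  if (is.matrix(arr)) return(arr + 0)
  d <- dim(arr)
  flat <- matrix(arr, d[1] * d[2], d[3])
  res <- flat[, 1]
  for (j in seq_len(d[3])[-1]) res <- pmax(res, flat[, j])
  matrix(res, d[1], d[2])
}

#' Rolling-ball background subtraction
#'
#' Estimates a smooth background as the grayscale opening of the image with a
#' ball-shaped structuring element of the given radius (the classic
#' rolling-ball model: the background is the surface traced by a ball rolled
#' beneath the intensity landscape), then subtracts it. Structures narrower
#' than the ball are preserved in the output; smooth background and gradients
#' are removed.
#'
#' @param image 2D numeric matrix.
#' @param radius_px Ball radius in pixels (> 0). The publication range for
#'   colony masking is 25-90 px (72-260 um at 2.9 um/px).
#' @return Background-subtracted image, elementwise `>= 0`.
#' @export
subtract_background <- function(image, radius_px) {
  check_positive(radius_px, "radius_px")
  bg <- cpp_rolling_ball(image, radius_px)
  pmax(image - bg, 0)
}

#' Disk median filter
#'
#' Replaces each pixel by the median over the disk of the given radius
#' (pixels with `dx^2 + dy^2 <= r^2`), reducing shot noise while keeping
#' edge contrast. The masking default of 2.5 px corresponds to 7.2 um at
#' 2.9 um/px.
#'
#' @param image 2D numeric matrix.
#' @param radius_px Disk radius in pixels (may be fractional).
#' @return Filtered image of the same size.
#' @export
median_filter <- function(image, radius_px = 2.5) {
  check_positive(radius_px, "radius_px")
  cpp_disk_median(image, radius_px)
}

#' Triangle automatic threshold
#'
#' Computes the histogram-based triangle threshold: over a 256-bin histogram
#' spanning the data range, draw the chord from the histogram peak to the far
#' end of the longer tail and pick the bin whose (bin index, count) point lies
#' furthest from that chord. Ties in the peak location break toward the lower
#' bin; ties in the distance break toward the lower bin.
#'
#' @param image 2D numeric matrix (or any numeric vector) with at least two
#'   distinct values.
#' @param n_bins Number of histogram bins (default 256).
#' @return The threshold as an intensity value (upper edge of the selected
#'   bin); foreground is `image > threshold`.
#' @export
triangle_threshold <- function(image, n_bins = 256) {
  x <- as.numeric(image)
  lo <- min(x); hi <- max(x)
  if (hi <= lo) stop("triangle threshold undefined for a constant image",
                     call. = FALSE)
  idx <- pmin(floor((x - lo) / (hi - lo) * n_bins), n_bins - 1)
  counts <- tabulate(idx + 1L, nbins = n_bins)
  thr_bin <- triangle_bin(counts)
  lo + (thr_bin + 1) * (hi - lo) / n_bins
}

# Triangle geometry on a raw histogram; returns the 0-based selected bin.
triangle_bin <- function(counts) {
  n_bins <- length(counts)
  peak <- which.max(counts) - 1L                 # ties -> lower bin
  nz <- which(counts > 0) - 1L
  lo_nz <- min(nz); hi_nz <- max(nz)
  # far tail endpoint: the nonzero extreme further from the peak
  tail_end <- if ((hi_nz - peak) >= (peak - lo_nz)) hi_nz else lo_nz
  if (tail_end == peak) return(peak)
  rng <- if (tail_end > peak) peak:tail_end else tail_end:peak
  x1 <- peak; y1 <- counts[peak + 1L]
  x2 <- tail_end; y2 <- counts[tail_end + 1L]
  nrm <- sqrt((x2 - x1)^2 + (y2 - y1)^2)
  d <- abs((y2 - y1) * (rng - x1) - (x2 - x1) * (counts[rng + 1L] - y1)) / nrm
  rng[which.max(d)]                              # ties -> bin closer to peak side start
}

#' Filter mask components by area and circularity
#'
#' Removes connected components (8-connectivity) of a binary image that are
#' smaller than `min_area_px2`. Circularity (`4*pi*A/P^2`, with the perimeter
#' counted as exposed pixel edges) is then used to remove small round specks,
#' which represent debris rather than filamentous colony: by default
#' (`mode = "exclude_round"`) components with circularity above the limit AND
#' area below `speck_cap_px2` are dropped. `mode = "include_round"` instead
#' keeps only components above the circularity limit (the literal reading of
#' some published protocols), and `mode = "off"` disables the circularity
#' rule.
#'
#' @param binary 2D logical (or 0/1) matrix.
#' @param min_area_px2 Minimum component area in pixels (default 200,
#'   ~1600 um^2 at 2.9 um/px).
#' @param circularity_limit Circularity cut in `[0, 1]` (default 0.9).
#' @param mode One of `"exclude_round"`, `"include_round"`, `"off"`.
#' @param speck_cap_px2 Area cap under which round components are treated as
#'   specks in `"exclude_round"` mode (default `2 * min_area_px2`).
#' @return A `colony_mask` object: list with logical `mask` and a
#'   `provenance` list recording the parameters and removed component counts.
#' @export
filter_components <- function(binary, min_area_px2 = 200,
                              circularity_limit = 0.9,
                              mode = c("exclude_round", "include_round", "off"),
                              speck_cap_px2 = 2 * min_area_px2) {
  mode <- match.arg(mode)
  check_count(min_area_px2, "min_area_px2", min = 1L)
  if (circularity_limit < 0 || circularity_limit > 1)
    stop("`circularity_limit` must be in [0, 1]", call. = FALSE)
  lab <- cpp_label_components(matrix(as.integer(binary != 0), nrow(binary)), 8L)
  nlab <- max(lab)
  removed_area <- 0L; removed_circ <- 0L
  keep <- rep(TRUE, nlab)
  if (nlab > 0) {
    area <- tabulate(lab[lab > 0], nbins = nlab)
    per <- cpp_component_perimeter(lab, nlab)
    circ <- 4 * pi * area / per^2
    small <- area < min_area_px2
    keep <- !small
    removed_area <- sum(small)
    if (mode == "exclude_round") {
      rnd <- keep & circ > circularity_limit & area < speck_cap_px2
      keep <- keep & !rnd; removed_circ <- sum(rnd)
    } else if (mode == "include_round") {
      rnd <- keep & circ <= circularity_limit
      keep <- keep & !rnd; removed_circ <- sum(rnd)
    }
  }
  mask <- matrix(FALSE, nrow(binary), ncol(binary))
  if (nlab > 0 && any(keep)) mask[lab %in% which(keep)] <- TRUE
  structure(list(mask = mask,
                 provenance = list(min_area_px2 = min_area_px2,
                                   circularity_limit = circularity_limit,
                                   circularity_mode = mode,
                                   speck_cap_px2 = speck_cap_px2,
                                   removed_small = removed_area,
                                   removed_circularity = removed_circ)),
            class = "colony_mask")
}

#' @export
print.colony_mask <- function(x, ...) {
  cat(sprintf("<colony_mask> %d x %d px, %d foreground px\n",
              nrow(x$mask), ncol(x$mask), sum(x$mask)))
  invisible(x)
}

#' Colony mask from a raw stack
#'
#' The full foreground-detection chain: maximum z-projection, rolling-ball
#' background subtraction, disk median filtering, triangle auto-threshold,
#' then component filtering by area and circularity.
#'
#' @param stack A [timelapse_stack()].
#' @param bg_radius_px Rolling-ball radius (default 25 px; use larger values
#'   for larger colonies, up to ~90 px).
#' @param median_radius_px Median filter disk radius (default 2.5 px).
#' @param min_area_px2,circularity_limit,mode Passed to [filter_components()].
#' @return A `colony_mask`; its provenance also records the projection/filter
#'   parameters and the threshold value used.
#' @export
build_colony_mask <- function(stack, bg_radius_px = 25, median_radius_px = 2.5,
                              min_area_px2 = 200, circularity_limit = 0.9,
                              mode = "exclude_round") {
  proj <- max_project(stack)
  sub <- subtract_background(proj, bg_radius_px)
  med <- median_filter(sub, median_radius_px)
  thr <- triangle_threshold(med)
  cm <- filter_components(med > thr, min_area_px2 = min_area_px2,
                          circularity_limit = circularity_limit, mode = mode)
  cm$provenance <- c(list(bg_radius_px = bg_radius_px,
                          median_radius_px = median_radius_px,
                          threshold = thr), cm$provenance)
  cm
}

#' Read/write a colony mask as an 8-bit TIFF (0/255)
#' @param mask A `colony_mask` or logical matrix.
#' @param path File path.
#' @export
write_mask <- function(mask, path) {
  m <- if (inherits(mask, "colony_mask")) mask$mask else mask
  tiff::writeTIFF(matrix(as.numeric(m), nrow(m)), path, bits.per.sample = 8L,
                  compression = "LZW", reduce = FALSE)
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  m <- tiff::readTIFF(path)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  structure(list(mask = m > 0.5, provenance = list(source = path)),
            class = "colony_mask")
}
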