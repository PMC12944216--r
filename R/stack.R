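#' Timelapse image stack
#'
#' Container for a 3D grayscale timelapse: a `height x width x frames`
#' intensity array plus acquisition metadata. The internal convention is
#' 0-based time (time in seconds = frame index * frame_interval, first frame
#' at t = 0) and `(row, column) = (y, x)` pixel coordinates.
#'
#' @param data 3D numeric array, `m` (rows) x `n` (columns) x `t` (frames).
#'   A matrix is accepted and treated as a single frame.
#' @param pixel_size Pixel size in micrometres per pixel (default 2.9, i.e.
#'   0.345 pixels/um widefield acquisition at 2x binning).
#' @param frame_interval Frame interval in seconds (default 1, i.e. 1 fps).
#' @param origin Frame index of recording start (time zero); default 0.
#' @return An object of class `timelapse_stack`.
#' @export
timelapse_stack <- function(data, pixel_size = 2.9, frame_interval = 1,
                            origin = 0) {
  if (is.matrix(data)) data <- array(data, c(dim(data), 1L))
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be an m x n x t array", call. = FALSE)
  if (any(dim(data) < 1L)) stop("all stack dimensions must be >= 1", call. = FALSE)
  check_positive(pixel_size, "pixel_size")
  check_positive(frame_interval, "frame_interval")
  structure(list(data = data, pixel_size = pixel_size,
                 frame_interval = frame_interval, origin = origin),
            class = "timelapse_stack")
}

#' @export
print.timelapse_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<timelapse_stack> %d x %d px, %d frames (%.3g um/px, %g s/frame)\n",
              d[1], d[2], d[3], x$pixel_size, x$frame_interval))
  invisible(x)
}

#' @export
dim.timelapse_stack <- function(x) dim(x$data)

#' Frame times of a stack, in seconds
#' @param stack A [timelapse_stack()].
#' @return Numeric vector of length `t`.
#' @export
frame_times <- function(stack) {
  (seq_len(dim(stack$data)[3]) - 1 + stack$origin) * stack$frame_interval
}

sidecar_path <- function(path) paste0(tools::file_path_sans_ext(path), ".json")

#' Read a multi-page TIFF timelapse stack
#'
#' Pixel values are returned on the stored integer scale (e.g. 0..65535 for
#' 16-bit input). Acquisition metadata (pixel size, frame interval) is taken
#' from a JSON sidecar written by [write_stack()] when present, else from the
#' arguments.
#'
#' @param path Path to a multi-page TIFF file.
#' @param pixel_size,frame_interval Metadata defaults used when no sidecar
#'   file is found.
#' @return A [timelapse_stack()].
#' @export
read_stack <- function(path, pixel_size = 2.9, frame_interval = 1) {
  if (!file.exists(path) || file.size(path) == 0)
    stop(sprintf("cannot read TIFF stack '%s': missing or empty file", path),
         call. = FALSE)
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, info = FALSE),
                    error = function(e)
                      stop(sprintf("cannot read TIFF stack '%s' at page 1: %s",
                                   path, conditionMessage(e)), call. = FALSE))
  if (is.matrix(pages)) pages <- list(pages)
  scale <- 65535; offset <- 0
  sc <- sidecar_path(path)
  if (file.exists(sc)) {
    meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
    if (!is.null(meta$pixel_size)) pixel_size <- meta$pixel_size
    if (!is.null(meta$frame_interval)) frame_interval <- meta$frame_interval
    if (!is.null(meta$scale)) scale <- meta$scale
    if (!is.null(meta$offset)) offset <- meta$offset
  }
  d <- dim(pages[[1]])
  for (i in seq_along(pages))
    if (is.null(dim(pages[[i]])) || !all(dim(pages[[i]])[1:2] == d[1:2]))
      stop(sprintf("cannot read TIFF stack '%s' at page %d: inconsistent frame size",
                   path, i), call. = FALSE)
  arr <- array(0, c(d[1], d[2], length(pages)))
  for (i in seq_along(pages)) {
    fr <- pages[[i]]
    if (length(dim(fr)) == 3L) fr <- fr[, , 1]     # drop extra channels
    arr[, , i] <- fr * scale + offset
  }
  if (scale == 65535 && offset == 0) arr <- round(arr)
  timelapse_stack(arr, pixel_size = pixel_size, frame_interval = frame_interval)
}

#' Write a stack as a multi-page TIFF with a JSON metadata sidecar
#'
#' Integer-valued stacks in `[0, 65535]` are written as 16-bit pages (the
#' round trip is then exact). Other data (e.g. Z-scores) are written as 32-bit
#' pages after an affine rescale to `[0, 1]`; the offset/scale is recorded in
#' the sidecar and undone by [read_stack()].
#'
#' @param stack A [timelapse_stack()] or a 2D/3D numeric array.
#' @param path Output TIFF path; the sidecar is written next to it with a
#'   `.json` extension.
#' @param bits 16 (integer) or 32 (float).
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path, bits = 16) {
  if (inherits(stack, "timelapse_stack")) {
    arr <- stack$data; px <- stack$pixel_size; fi <- stack$frame_interval
  } else {
    arr <- stack; px <- 2.9; fi <- 1
    if (is.matrix(arr)) arr <- array(arr, c(dim(arr), 1L))
  }
  t <- dim(arr)[3]
  if (bits == 16) {
    scale <- 65535; offset <- 0
    pages <- lapply(seq_len(t), function(i) clamp(round(arr[, , i]), 0, 65535) / 65535)
    bps <- 16L
  } else {
    lo <- min(arr); hi <- max(arr)
    offset <- lo; scale <- if (hi > lo) hi - lo else 1
    pages <- lapply(seq_len(t), function(i) (arr[, , i] - offset) / scale)
    bps <- 32L
  }
  tiff::writeTIFF(pages, path, bits.per.sample = bps, compression = "LZW",
                  reduce = FALSE)
  jsonlite::write_json(list(pixel_size = px, frame_interval = fi,
                            scale = scale, offset = offset, bits = bps),
                       sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Crop a stack to a pixel rectangle
#'
#' @param stack A [timelapse_stack()].
#' @param rect Integer vector `c(row0, col0, height, width)` with 0-based
#'   top-left corner.
#' @return The cropped [timelapse_stack()] (all frames cropped identically,
#'   metadata preserved).
#' @export
crop_stack <- function(stack, rect) {
  stopifnot(inherits(stack, "timelapse_stack"), length(rect) == 4L)
  d <- dim(stack$data)
  r0 <- rect[1]; c0 <- rect[2]; h <- rect[3]; w <- rect[4]
  if (r0 < 0 || c0 < 0 || h < 1 || w < 1 || r0 + h > d[1] || c0 + w > d[2])
    stop(sprintf("crop rectangle [%d,%d,%d,%d] exceeds %d x %d frame bounds",
                 r0, c0, h, w, d[1], d[2]), call. = FALSE)
  out <- stack
  out$data <- stack$data[(r0 + 1):(r0 + h), (c0 + 1):(c0 + w), , drop = FALSE]
  out
}
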