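#' Acquisition model
#'
#' Camera and optics parameters used to render synthetic stacks: widefield
#' defaults of 2.9 um/pixel (0.345 px/um), 1 frame/s, a 1.1 um PSF
#' (0.61 * lambda / NA with GCaMP emission and a 0.28 NA objective), shot
#' noise as Poisson counts with a photon gain, Gaussian read noise, and a
#' smooth background with an optional linear gradient. Default noise gives a
#' per-pixel SNR of about 10 at a typical baseline of 300 counts.
#'
#' @param pixel_size um/pixel (default 2.9).
#' @param frame_interval s/frame (default 1).
#' @param psf_diameter_um PSF FWHM in um (default 1.1).
#' @param poisson_gain Camera counts per photon; 0 disables shot noise.
#' @param read_noise_sd Gaussian read noise SD in counts; 0 disables.
#' @param background Mean background level, counts.
#' @param background_gradient Relative peak-to-peak linear gradient of the
#'   background across the frame (0 = flat).
#' @param frame_px Optional fixed frame size `c(rows, cols)`; by default the
#'   frame is sized to the colony with a margin.
#' @return An `acquisition_model` list.
#' @export
acquisition_model <- function(pixel_size = 2.9, frame_interval = 1,
                              psf_diameter_um = 1.1, poisson_gain = 3,
                              read_noise_sd = 5, background = 100,
                              background_gradient = 0.1, frame_px = NULL) {
  for (nm in c("pixel_size", "frame_interval", "psf_diameter_um"))
    check_positive(get(nm), nm)
  if (poisson_gain < 0 || read_noise_sd < 0 || background < 0)
    stop("noise and background parameters must be nonnegative", call. = FALSE)
  structure(as.list(environment())[c("pixel_size", "frame_interval",
                                     "psf_diameter_um", "poisson_gain",
                                     "read_noise_sd", "background",
                                     "background_gradient", "frame_px")],
            class = "acquisition_model")
}

# Rasterize a colony geometry: per-pixel region id and membership weight.
# Pixels belong to the region whose filament centerline they are closest to
# (relative to the local half-width); intensity tapers toward cell borders
# with a cosine falloff over ~2 px down to `w_min`, outside which pixels are
# background. Returns label matrix, weight matrix and the um->px transform.
rasterize_geometry <- function(geometry, acq) {
  px <- acq$pixel_size
  allpts <- do.call(rbind, geometry$filaments)
  wmax <- max(geometry$cells$width_um) / 2
  margin <- wmax + 3 * px
  x0 <- min(allpts[, 1]) - margin; y0 <- min(allpts[, 2]) - margin
  ncol_px <- ceiling((max(allpts[, 1]) + margin - x0) / px)
  nrow_px <- ceiling((max(allpts[, 2]) + margin - y0) / px)
  if (!is.null(acq$frame_px)) {
    if (nrow_px > acq$frame_px[1] || ncol_px > acq$frame_px[2]) {
      ext <- apply(allpts, 1, function(q) max(abs(q)))
      stop(sprintf("colony geometry exceeds the %d x %d px frame (filament %d extends furthest)",
                   acq$frame_px[1], acq$frame_px[2],
                   which.max(vapply(geometry$filaments,
                                    function(f) max(abs(f)), 0))),
           call. = FALSE)
    }
    nrow_px <- acq$frame_px[1]; ncol_px <- acq$frame_px[2]
  }
  # pixel centers in um
  xc <- x0 + (seq_len(ncol_px) - 0.5) * px
  yc <- y0 + (seq_len(nrow_px) - 0.5) * px
  best_ratio <- matrix(Inf, nrow_px, ncol_px)   # d / h, lower is deeper inside
  best_fil <- matrix(0L, nrow_px, ncol_px)
  best_s <- matrix(0, nrow_px, ncol_px)
  best_d <- matrix(Inf, nrow_px, ncol_px)
  for (fi in seq_along(geometry$filaments)) {
    pts <- geometry$filaments[[fi]]
    cells_f <- geometry$cells[geometry$cells$filament_id == fi, ]
    hw <- cells_f$width_um / 2
    seg <- diff(pts)
    lens <- sqrt(rowSums(seg^2))
    cum <- c(0, cumsum(lens))
    L <- cum[length(cum)]
    hmax <- max(hw)
    for (si in seq_len(nrow(seg))) {
      a <- pts[si, ]; v <- seg[si, ]; sl <- lens[si]
      # bounding box of the segment, expanded by the half-width
      jr <- which(xc >= min(a[1], a[1] + v[1]) - hmax - px &
                  xc <= max(a[1], a[1] + v[1]) + hmax + px)
      ir <- which(yc >= min(a[2], a[2] + v[2]) - hmax - px &
                  yc <= max(a[2], a[2] + v[2]) + hmax + px)
      if (!length(jr) || !length(ir)) next
      gx <- matrix(xc[jr], length(ir), length(jr), byrow = TRUE)
      gy <- matrix(yc[ir], length(ir), length(jr))
      tt <- clamp(((gx - a[1]) * v[1] + (gy - a[2]) * v[2]) / sl^2, 0, 1)
      dx <- gx - (a[1] + tt * v[1]); dy <- gy - (a[2] + tt * v[2])
      d <- sqrt(dx^2 + dy^2)
      s <- clamp(cum[si] + tt * sl, 0, L - 1e-9)
      ci <- findInterval(s, c(cells_f$s0_um[1], cells_f$s1_um),
                         rightmost.closed = TRUE, all.inside = TRUE)
      h <- matrix(hw[ci], length(ir), length(jr))
      ratio <- d / h
      sub <- best_ratio[ir, jr, drop = FALSE]
      upd <- ratio < sub & ratio < 1
      if (any(upd)) {
        sub[upd] <- ratio[upd]; best_ratio[ir, jr] <- sub
        bf <- best_fil[ir, jr, drop = FALSE]; bf[upd] <- fi; best_fil[ir, jr] <- bf
        bs <- best_s[ir, jr, drop = FALSE]; bs[upd] <- s[upd]; best_s[ir, jr] <- bs
        bd <- best_d[ir, jr, drop = FALSE]; bd[upd] <- d[upd]; best_d[ir, jr] <- bd
      }
    }
  }
  # region labels and taper weights
  labels <- matrix(0L, nrow_px, ncol_px)
  weight <- matrix(0, nrow_px, ncol_px)
  w_min <- 0.15
  taper_um <- 2 * px
  inside <- which(best_fil > 0)
  for (fi in unique(best_fil[inside])) {
    idx <- which(best_fil == fi)
    s <- best_s[idx]
    cells_f <- geometry$cells[geometry$cells$filament_id == fi, ]
    regs_f <- geometry$regions[geometry$regions$filament_id == fi, ]
    ri <- findInterval(s, c(regs_f$s0_um[1], regs_f$s1_um),
                       rightmost.closed = TRUE, all.inside = TRUE)
    labels[idx] <- regs_f$region_id[ri]
    ci <- findInterval(s, c(cells_f$s0_um[1], cells_f$s1_um),
                       rightmost.closed = TRUE, all.inside = TRUE)
    h <- cells_f$width_um[ci] / 2
    tw <- pmin(taper_um, 0.8 * h)
    d <- best_d[idx]
    flat <- h - tw
    w <- ifelse(d <= flat, 1,
                w_min + (1 - w_min) * 0.5 * (1 + cos(pi * (d - flat) / tw)))
    weight[idx] <- w
  }
  list(labels = labels, weight = weight,
       origin_um = c(x0, y0), dim = c(nrow_px, ncol_px))
}

#' Render a synthetic timelapse stack
#'
#' Forward model: each frame is `background field + sum over regions of
#' membership weight x F0 x (1 + baseline elevation + sum of Gaussian
#' waves)`, convolved with the Gaussian PSF, with Poisson shot noise and
#' Gaussian read noise applied. Intensity tapers toward cell borders. With
#' noise disabled the continuous (unquantized) intensities are returned so
#' closed-form checks are exact; with noise on, values are rounded to
#' integer camera counts in `[0, 65535]`.
#'
#' @param geometry A `colony_geometry`.
#' @param program A `wave_program` from [schedule_waves()].
#' @param acq An [acquisition_model()].
#' @param duration_s Recording duration in seconds (>= 1); defaults to the
#'   program's protocol duration.
#' @param seed Integer seed for the noise stream.
#' @return A list: `stack` (a [timelapse_stack()]) and `ground_truth` (list
#'   with `label_map` (a [roi_label_map()]), `weight` matrix, `program`,
#'   `protocol`, and `regions` table).
#' @export
render_stack <- function(geometry, program, acq = acquisition_model(),
                         duration_s = NULL, seed = 0) {
  if (is.null(duration_s)) duration_s <- protocol_duration(program$protocol)
  check_positive(duration_s, "duration_s")
  ras <- rasterize_geometry(geometry, acq)
  m <- ras$dim[1]; n <- ras$dim[2]
  nt <- max(1L, floor(duration_s / acq$frame_interval))
  times <- (seq_len(nt) - 1) * acq$frame_interval
  # background field with linear gradient
  gx <- (seq_len(n) - (n + 1) / 2) / n
  gy <- (seq_len(m) - (m + 1) / 2) / m
  bg <- as.vector(acq$background *
    (1 + acq$background_gradient * (outer(gy, gx, `+`) / 2)))
  R <- length(program$f0)
  reg_idx <- lapply(seq_len(R), function(r) which(ras$labels == r))
  tr <- vapply(seq_len(R), function(r)
    program$f0[r] * (1 + programmed_trace(program, r, times)), numeric(nt))
  fwhm_px <- acq$psf_diameter_um / acq$pixel_size
  psf <- if (fwhm_px >= 0.2)
    suppressWarnings(gaussian_psf(acq$psf_diameter_um, acq$pixel_size))
  else NULL
  noisy <- acq$poisson_gain > 0 || acq$read_noise_sd > 0
  out <- if (noisy) array(0L, c(m, n, nt)) else array(0, c(m, n, nt))
  # render in frame chunks to bound peak memory
  chunk <- 256L
  with_seed(seed, {
    for (c0 in seq(1L, nt, by = chunk)) {
      c1 <- min(nt, c0 + chunk - 1L)
      nc <- c1 - c0 + 1L
      M <- matrix(bg, m * n, nc)
      for (r in seq_len(R)) {
        if (!length(reg_idx[[r]])) next
        M[reg_idx[[r]], ] <- M[reg_idx[[r]], ] +
          ras$weight[reg_idx[[r]]] %o% tr[c0:c1, r]
      }
      dim(M) <- c(m, n, nc)
      if (!is.null(psf)) M <- conv_small(M, psf)
      if (noisy) {
        if (acq$poisson_gain > 0)
          M <- array(rpois(length(M), M / acq$poisson_gain) * acq$poisson_gain,
                     dim(M))
        if (acq$read_noise_sd > 0)
          M <- M + rnorm(length(M), 0, acq$read_noise_sd)
        out[, , c0:c1] <- as.integer(clamp(round(M), 0, 65535))
      } else {
        out[, , c0:c1] <- M
      }
    }
  })
  stack <- timelapse_stack(out, pixel_size = acq$pixel_size,
                           frame_interval = acq$frame_interval)
  gt <- structure(list(label_map = roi_label_map(ras$labels, acq$pixel_size),
                       weight = ras$weight, program = program,
                       protocol = program$protocol,
                       regions = geometry$regions),
                  class = "ground_truth")
  list(stack = stack, ground_truth = gt)
}

#' Simulate a colony recording end to end
#'
#' Convenience wrapper: builds a geometry, schedules waves under a stimulus
#' protocol, and renders the stack. The three stages use seeds derived from
#' `seed` so the whole simulation is reproducible from one integer.
#'
#' @param seed Integer master seed.
#' @param n_filaments,cells_per_filament,branch_prob Passed to
#'   [build_geometry()].
#' @param protocol A [stimulus_protocol()].
#' @param params A [wave_params()].
#' @param acq An [acquisition_model()].
#' @param out_dir Optional directory: when given, writes `stack.tif` (+ JSON
#'   sidecar), `labels.tif`, `protocol.json` and `ground_truth.json`
#'   (schedule and region table) into it.
#' @return As [render_stack()], plus `geometry` and `program`.
#' @export
simulate_colony <- function(seed, n_filaments = 4, cells_per_filament = 5,
                            branch_prob = 0.15,
                            protocol = pulse_train(10, 60, 240, first_on_s = 120),
                            params = wave_params(),
                            acq = acquisition_model(), out_dir = NULL) {
  geom <- build_geometry(seed, n_filaments, cells_per_filament, branch_prob)
  prog <- schedule_waves(geom, protocol, params, seed = seed + 1L)
  rend <- render_stack(geom, prog, acq, seed = seed + 2L)
  out <- c(rend, list(geometry = geom, program = prog))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_stack(rend$stack, file.path(out_dir, "stack.tif"))
    lab <- rend$ground_truth$label_map$labels
    tiff::writeTIFF(lab / 65535, file.path(out_dir, "labels.tif"),
                    bits.per.sample = 16L, compression = "LZW", reduce = FALSE)
    write_protocol(protocol, file.path(out_dir, "protocol.json"))
    jsonlite::write_json(list(seed = seed,
                              waves = rend$ground_truth$program$waves,
                              f0 = rend$ground_truth$program$f0,
                              regions = geom$regions),
                         file.path(out_dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}
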