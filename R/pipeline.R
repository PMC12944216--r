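#' Pipeline configuration
#'
#' All stage parameters with their defaults, serializable to/from JSON.
#' Unknown keys are rejected so typos cannot silently fall back to defaults.
#'
#' @param bg_radius_px Rolling-ball radius for masking (px).
#' @param median_radius_px Median filter disk radius for masking (px).
#' @param mask_min_area_px2 Minimum mask component area (px^2).
#' @param circularity_limit,circularity_mode Mask circularity rule.
#' @param psf_diameter_um PSF FWHM for deconvolution (um).
#' @param iterations Richardson-Lucy iterations.
#' @param opening_radius_px Background-field opening radius (px).
#' @param mean_roi_area_px2 Mean desired ROI area for the initial k (px^2).
#' @param k_scale Multiplier applied to the initial cluster count (1 =
#'   the area-based estimate).
#' @param replicates k-means random restarts.
#' @param min_area_px2 Minimum ROI area after splitting (px^2).
#' @param baseline_percentile Percentile for the robust F0 baseline.
#' @param exclude_nonresponsive Apply the non-responsive ROI exclusion rule.
#' @param response_threshold,response_window_s Exclusion rule parameters.
#' @param mad_factor,min_prominence,merge_s Wave detector parameters.
#' @param max_lag_s Cross-correlation lag range (s).
#' @param seed Integer seed for the clustering.
#' @return A `run_config` list.
#' @export
run_config <- function(bg_radius_px = 25, median_radius_px = 2.5,
                       mask_min_area_px2 = 200, circularity_limit = 0.9,
                       circularity_mode = "exclude_round",
                       psf_diameter_um = 1.1, iterations = 10,
                       opening_radius_px = 15,
                       mean_roi_area_px2 = 150, k_scale = 1,
                       replicates = 10, min_area_px2 = 12,
                       baseline_percentile = 1,
                       exclude_nonresponsive = TRUE,
                       response_threshold = 1.0, response_window_s = 300,
                       mad_factor = 0.35, min_prominence = 0.25,
                       merge_s = 10, max_lag_s = 120, seed = 0) {
  structure(as.list(environment()), class = "run_config")
}

#' Read/write a run configuration as JSON
#' @param config A [run_config()].
#' @param path File path.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(run_config))
  bad <- setdiff(names(x), known)
  if (length(bad))
    stop(sprintf("unknown config keys: %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  do.call(run_config, x)
}

#' Run the full analysis pipeline
#'
#' Executes mask -> deconvolve -> background-correct -> Z-normalize ->
#' cluster -> split -> prune -> traces -> (exclusion) -> wave detection ->
#' pulse metrics on a raw stack, and assembles a reproducibility manifest of
#' every stage's parameters. Identical input, config and seed give identical
#' outputs.
#'
#' @param stack A [timelapse_stack()].
#' @param protocol A [stimulus_protocol()].
#' @param config A [run_config()].
#' @return A `pipeline_result` list: `mask`, `label_map`, `traces`, `waves`,
#'   `pulse` (NULL when the protocol has no pulses), `exclusions`, and
#'   `manifest`.
#' @export
run_all <- function(stack, protocol, config = run_config()) {
  cfg <- config
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))
  }
  mask <- stage("mask", build_colony_mask(
    stack, cfg$bg_radius_px, cfg$median_radius_px,
    cfg$mask_min_area_px2, cfg$circularity_limit, cfg$circularity_mode))
  if (!any(mask$mask)) stop("[mask] no colony foreground detected", call. = FALSE)
  corr <- stage("normalize", normalize_stack(
    stack, mask, cfg$psf_diameter_um, cfg$iterations, cfg$opening_radius_px))
  pm <- stage("normalize", zscore_pixels(corr, mask))
  seg <- stage("segment", {
    k <- max(1L, round(initial_cluster_count(sum(mask$mask),
                                             cfg$mean_roi_area_px2) * cfg$k_scale))
    assign <- cluster_pixels(pm, k, seed = cfg$seed,
                             replicates = cfg$replicates)
    labels <- split_disconnected(assign, mask)
    prune_small(labels, cfg$min_area_px2)
  })
  traces <- stage("traces", extract_traces(corr, seg, stack$frame_interval,
                                           cfg$baseline_percentile))
  exclusions <- NULL
  if (cfg$exclude_nonresponsive && nrow(protocol) >= 1) {
    traces <- stage("traces", exclude_nonresponsive(
      traces, protocol, cfg$response_threshold, cfg$response_window_s))
    exclusions <- attr(traces, "exclusions")
    if (length(traces$roi_id) == 0)
      stop("[traces] every ROI was excluded as non-responsive", call. = FALSE)
  }
  waves <- stage("waves", detect_all_waves(traces, cfg$mad_factor,
                                           cfg$min_prominence, cfg$merge_s))
  if (nrow(waves) == 0)
    warning("no calcium waves detected in any ROI")
  pulse <- NULL
  if (nrow(protocol) >= 1)
    pulse <- stage("waves", pulse_metrics(waves, traces, protocol))
  manifest <- list(package = "mosswave",
                   version = as.character(packageVersion("mosswave")),
                   config = unclass(cfg),
                   protocol = list(duration_s = protocol_duration(protocol),
                                   pulses = as.data.frame(protocol)),
                   stack_dim = dim(stack$data),
                   pixel_size = stack$pixel_size,
                   frame_interval = stack$frame_interval,
                   n_foreground_px = sum(mask$mask),
                   n_rois = length(traces$roi_id),
                   n_waves = nrow(waves),
                   mask_provenance = mask$provenance)
  structure(list(mask = mask, label_map = seg, traces = traces, waves = waves,
                 pulse = pulse, exclusions = exclusions, manifest = manifest),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> %d ROIs, %d waves from a %s stack\n",
              length(x$traces$roi_id), nrow(x$waves),
              paste(x$manifest$stack_dim, collapse = " x ")))
  invisible(x)
}

#' Write pipeline results to a directory
#'
#' Writes `traces.csv` (first column time in seconds, one column per ROI of
#' normalized dF/F0), `traces_raw.csv` (same layout, raw integrated
#' fluorescence), `waves.csv` (one row per wave event with all shape
#' metrics), and `manifest.json`. All writers are deterministic: fixed
#' column order and fixed 6-significant-digit float formatting, so identical
#' inputs give byte-identical files.
#'
#' @param traces A `roi_trace_set`.
#' @param waves A `wave_table` (or event data frame).
#' @param path Output directory (created if needed).
#' @param manifest Optional manifest list to write alongside.
#' @return Character vector of files written, invisibly.
#' @export
write_results <- function(traces, waves, path, manifest = NULL) {
  if (nrow(waves) > 0) {
    orphan <- setdiff(unique(waves$roi_id), traces$roi_id)
    if (length(orphan))
      stop(sprintf("wave table references ROI ids absent from traces: %s",
                   paste(orphan, collapse = ", ")), call. = FALSE)
  }
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  write_trace_csv <- function(mat, file) {
    hdr <- c("time_s", sprintf("roi_%d", traces$roi_id))
    rows <- vapply(seq_along(traces$time), function(i)
      paste(c(format_num(traces$time[i]), format_num(mat[i, ])), collapse = ","),
      "")
    writeLines(c(paste(hdr, collapse = ","), rows), file)
    file
  }
  files <- c(files, write_trace_csv(traces$norm, file.path(path, "traces.csv")))
  files <- c(files, write_trace_csv(traces$f, file.path(path, "traces_raw.csv")))
  wcols <- c("roi_id", "peak_time", "peak_value", "prominence", "onset_time",
             "end_time", "fw10_duration", "rise_time", "fall_time",
             "baseline_level", "truncated_left", "truncated_right")
  wf <- file.path(path, "waves.csv")
  rows <- vapply(seq_len(nrow(waves)), function(i)
    paste(vapply(wcols, function(cn) {
      v <- waves[[cn]][i]
      if (is.logical(v)) as.character(v) else format_num(v)
    }, ""), collapse = ","), "")
  writeLines(c(paste(wcols, collapse = ","), rows), wf)
  files <- c(files, wf)
  if (!is.null(manifest)) {
    mf <- file.path(path, "manifest.json")
    jsonlite::write_json(manifest, mf, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    files <- c(files, mf)
  }
  invisible(files)
}

#' Read a traces CSV written by [write_results()]
#' @param path Path to `traces.csv`.
#' @param frame_interval Seconds per frame override; inferred from the time
#'   column by default.
#' @return A `roi_trace_set` (normalized traces only; `f` equals `norm` and
#'   `f0` is 1 for all ROIs).
#' @export
read_traces <- function(path, frame_interval = NULL) {
  df <- read.csv(path, check.names = FALSE)
  time <- df[[1]]
  mat <- as.matrix(df[, -1, drop = FALSE])
  ids <- as.integer(sub("^roi_", "", colnames(mat)))
  fi <- if (!is.null(frame_interval)) frame_interval
        else if (length(time) > 1) diff(time[1:2]) else 1
  structure(list(time = time, f = mat, norm = mat,
                 f0 = rep(1, ncol(mat)),
                 area_px2 = rep(NA_real_, ncol(mat)),
                 centroid = matrix(NA_real_, ncol(mat), 2),
                 roi_id = ids, frame_interval = fi),
            class = "roi_trace_set")
}
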