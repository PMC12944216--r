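#' Detect calcium waves in a normalized ROI trace
#'
#' Local maxima whose topographic prominence (height above the higher of the
#' two flanking minima, walking out to the nearest higher point or the trace
#' boundary) reaches `0.35 * MAD` of the full trace become wave events; the
#' MAD is unscaled (`median(|x - median(x)|)`, no consistency factor). An
#' absolute prominence floor (default 0.25 dF/F0: above the largest noise
#' excursions of small-ROI traces at typical camera noise, yet well below the
#' smallest reported wave amplitudes of ~0.7) keeps pure-noise ripples out.
#' Peaks
#' closer than `merge_s` are merged, keeping the higher.
#'
#' For each event, the onset/end are the 10%-of-prominence crossings (linear
#' interpolation) on the rising/falling flank, measured above the peak's base
#' level (peak minus prominence); FW10 is their span, and rise/fall times are
#' the 10%-to-90% crossing spans per flank. Events whose flanks never reach
#' the 10% level before the search bound are flagged `truncated` (boundary)
#' or bounded at the flanking minimum.
#'
#' @param trace Numeric normalized trace (dF/F0), length >= 3.
#' @param frame_interval Seconds per frame (default 1).
#' @param mad_factor Prominence threshold as a multiple of the trace MAD
#'   (default 0.35).
#' @param min_prominence Absolute prominence floor in dF/F0 units
#'   (default 0.25).
#' @param merge_s Minimum peak separation in seconds; closer peaks are merged
#'   keeping the higher (default 10).
#' @param roi_id Optional id stored in the result.
#' @return A data frame of wave events with columns `roi_id`, `peak_time`,
#'   `peak_value`, `prominence`, `onset_time`, `end_time`, `fw10_duration`,
#'   `rise_time`, `fall_time`, `baseline_level`, `truncated_left`,
#'   `truncated_right` (times in seconds). Zero rows if nothing qualifies.
#' @export
detect_waves <- function(trace, frame_interval = 1, mad_factor = 0.35,
                         min_prominence = 0.25, merge_s = 10, roi_id = 1L) {
  n <- length(trace)
  empty <- data.frame(roi_id = numeric(0), peak_time = numeric(0),
                      peak_value = numeric(0), prominence = numeric(0),
                      onset_time = numeric(0), end_time = numeric(0),
                      fw10_duration = numeric(0), rise_time = numeric(0),
                      fall_time = numeric(0), baseline_level = numeric(0),
                      truncated_left = logical(0), truncated_right = logical(0))
  if (n < 3) return(empty)
  x <- as.numeric(trace)
  pk <- local_maxima(x)
  if (!length(pk)) return(empty)
  pr <- vapply(pk, function(i) prominence_at(x, i), 0)
  thr <- max(mad_factor * mad_raw(x), min_prominence)
  keep <- pr >= thr
  pk <- pk[keep]; pr <- pr[keep]
  if (!length(pk)) return(empty)
  # merge peaks closer than merge_s, keeping the higher
  min_sep <- merge_s / frame_interval
  o <- order(x[pk], decreasing = TRUE)
  sel <- logical(length(pk))
  taken <- numeric(0)
  for (j in o) {
    if (!length(taken) || all(abs(pk[j] - taken) >= min_sep)) {
      sel[j] <- TRUE
      taken <- c(taken, pk[j])
    }
  }
  pk <- pk[sel]; pr <- pr[sel]
  o <- order(pk); pk <- pk[o]; pr <- pr[o]

  ev <- lapply(seq_along(pk), function(j) {
    i <- pk[j]
    base <- x[i] - pr[j]
    b <- base_bounds(x, i)
    lv10 <- base + 0.1 * pr[j]
    lv90 <- base + 0.9 * pr[j]
    on10 <- cross_left(x, i, b$left, lv10)
    on90 <- cross_left(x, i, b$left, lv90)
    off10 <- cross_right(x, i, b$right, lv10)
    off90 <- cross_right(x, i, b$right, lv90)
    data.frame(roi_id = roi_id,
               peak_time = (i - 1) * frame_interval,
               peak_value = x[i], prominence = pr[j],
               onset_time = (on10$pos - 1) * frame_interval,
               end_time = (off10$pos - 1) * frame_interval,
               fw10_duration = (off10$pos - on10$pos) * frame_interval,
               rise_time = (on90$pos - on10$pos) * frame_interval,
               fall_time = (off10$pos - off90$pos) * frame_interval,
               baseline_level = base,
               truncated_left = on10$truncated,
               truncated_right = off10$truncated)
  })
  do.call(rbind, ev)
}

# indices of strict local maxima; plateaus contribute their center
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3) return(integer(0))
  out <- integer(0)
  i <- 2L
  while (i <= n - 1L) {
    if (x[i] > x[i - 1L]) {
      j <- i
      while (j < n && x[j + 1L] == x[j]) j <- j + 1L
      if (j < n && x[j + 1L] < x[j]) out <- c(out, as.integer(floor((i + j) / 2)))
      i <- j + 1L
    } else i <- i + 1L
  }
  out
}

# topographic prominence of the peak at index i
prominence_at <- function(x, i) {
  n <- length(x)
  lmin <- x[i]; j <- i
  while (j > 1 && x[j - 1] <= x[i]) { j <- j - 1; lmin <- min(lmin, x[j]) }
  rmin <- x[i]; j <- i
  while (j < n && x[j + 1] <= x[i]) { j <- j + 1; rmin <- min(rmin, x[j]) }
  x[i] - max(lmin, rmin)
}

# search bounds for crossings: the flanking minima positions within the
# peak's base (out to the nearest higher terrain or the boundary)
base_bounds <- function(x, i) {
  n <- length(x)
  j <- i; lpos <- i; lmin <- x[i]
  while (j > 1 && x[j - 1] <= x[i]) {
    j <- j - 1
    if (x[j] < lmin) { lmin <- x[j]; lpos <- j }
  }
  j <- i; rpos <- i; rmin <- x[i]
  while (j < n && x[j + 1] <= x[i]) {
    j <- j + 1
    if (x[j] < rmin) { rmin <- x[j]; rpos <- j }
  }
  list(left = lpos, right = rpos)
}

# last downward crossing of `level` left of peak i, searching down to bound;
# returns fractional (1-based) position and truncation flag
cross_left <- function(x, i, bound, level) {
  j <- i
  while (j > bound && x[j - 1] > level) j <- j - 1
  if (j == bound || x[j - 1] > level)
    return(list(pos = bound, truncated = bound == 1))
  frac <- (x[j] - level) / (x[j] - x[j - 1])
  list(pos = j - frac, truncated = FALSE)
}

cross_right <- function(x, i, bound, level) {
  n <- length(x)
  j <- i
  while (j < bound && x[j + 1] > level) j <- j + 1
  if (j == bound || x[j + 1] > level)
    return(list(pos = bound, truncated = bound == n))
  frac <- (x[j] - level) / (x[j] - x[j + 1])
  list(pos = j + frac, truncated = FALSE)
}

#' Detect waves across all ROIs of a trace set
#'
#' Runs [detect_waves()] on every normalized ROI trace and assembles a wave
#' table, including per-wave 120 s snippets (60 s before and after each
#' peak, normalized to the peak intensity) used for wave-shape overlays.
#'
#' @param traces A `roi_trace_set`.
#' @inheritParams detect_waves
#' @param window_s Snippet half-window in seconds (default 60, i.e. 121
#'   samples at 1 fps).
#' @return A `wave_table`: the combined event data frame with attributes
#'   `snippets` (events x samples matrix) and `frame_interval`.
#' @export
detect_all_waves <- function(traces, mad_factor = 0.35, min_prominence = 0.25,
                             merge_s = 10, window_s = 60) {
  fi <- traces$frame_interval
  evs <- lapply(seq_along(traces$roi_id), function(j)
    detect_waves(traces$norm[, j], fi, mad_factor, min_prominence,
                 merge_s, roi_id = traces$roi_id[j]))
  tab <- do.call(rbind, evs)
  if (is.null(tab) || nrow(tab) == 0) {
    tab <- detect_waves(numeric(0))
    attr(tab, "snippets") <- matrix(0, 0, 2 * round(window_s / fi) + 1)
    attr(tab, "frame_interval") <- fi
    class(tab) <- c("wave_table", "data.frame")
    return(tab)
  }
  half <- round(window_s / fi)
  nt <- length(traces$time)
  snip <- t(vapply(seq_len(nrow(tab)), function(e) {
    j <- match(tab$roi_id[e], traces$roi_id)
    p <- round(tab$peak_time[e] / fi) + 1
    idx <- (p - half):(p + half)
    v <- rep(NA_real_, length(idx))
    ok <- idx >= 1 & idx <= nt
    v[ok] <- traces$norm[idx[ok], j]
    pv <- traces$norm[p, j]
    if (pv != 0) v / pv else v
  }, numeric(2 * half + 1)))
  attr(tab, "snippets") <- snip
  attr(tab, "frame_interval") <- fi
  class(tab) <- c("wave_table", "data.frame")
  tab
}

#' Inter-wave intervals, frequency and CV per ROI
#'
#' Peak-to-peak intervals between consecutive waves of the same ROI, the
#' oscillation frequency (`60 / mean interval` per minute), and the interval
#' coefficient of variation (sample SD / mean, percent). ROIs need at least
#' 2 events for intervals and 3 for a CV; others yield empty/NA results, not
#' errors.
#'
#' @param waves A `wave_table` or event data frame with `roi_id`, `peak_time`.
#' @return A list with `intervals` (data frame: roi_id, interval_s) and
#'   `per_roi` (data frame: roi_id, n_waves, mean_interval_s,
#'   freq_per_min, cv_pct).
#' @export
wave_intervals <- function(waves) {
  ids <- unique(waves$roi_id)
  iv <- lapply(ids, function(id) {
    pt <- sort(waves$peak_time[waves$roi_id == id])
    if (length(pt) < 2) return(NULL)
    data.frame(roi_id = id, interval_s = diff(pt))
  })
  intervals <- do.call(rbind, iv)
  if (is.null(intervals))
    intervals <- data.frame(roi_id = numeric(0), interval_s = numeric(0))
  per_roi <- do.call(rbind, lapply(ids, function(id) {
    x <- intervals$interval_s[intervals$roi_id == id]
    nw <- sum(waves$roi_id == id)
    data.frame(roi_id = id, n_waves = nw,
               mean_interval_s = if (length(x) >= 1) mean(x) else NA_real_,
               freq_per_min = if (length(x) >= 1) 60 / mean(x) else NA_real_,
               cv_pct = if (length(x) >= 2) 100 * sd(x) / mean(x) else NA_real_)
  }))
  list(intervals = intervals, per_roi = per_roi)
}

#' Response latency to a stimulus onset
#'
#' Latency from stimulus onset to the initiation (10%-of-prominence rising
#' crossing) of the first wave whose onset follows the stimulus. Returns
#' `NA` (missing response) when no wave starts after the onset.
#'
#' @param events Wave events of one ROI (data frame with `onset_time`).
#' @param onset_s Stimulus onset time, seconds.
#' @param window_s Optional cap: only waves starting within `window_s` of the
#'   onset count as responses (default `Inf`).
#' @return Latency in seconds, or `NA_real_`.
#' @export
response_latency <- function(events, onset_s, window_s = Inf) {
  cand <- events$onset_time[events$onset_time > onset_s &
                            events$onset_time <= onset_s + window_s]
  if (!length(cand)) return(NA_real_)
  min(cand) - onset_s
}

#' Instantaneous probability of a calcium wave
#'
#' `P(t)` is the fraction of ROIs that are inside a wave at time `t`, where
#' "inside" means `t` lies within the FW10 span `[onset, end]` of one of the
#' ROI's events.
#'
#' @param waves A `wave_table` (or event data frame).
#' @param n_rois Total number of ROIs the probability is taken over.
#' @param times Numeric vector of evaluation times (seconds).
#' @return Numeric vector of probabilities in `[0, 1]`, one per time.
#' @export
wave_probability <- function(waves, n_rois, times) {
  check_count(n_rois, "n_rois", min = 1L)
  if (nrow(waves) == 0) return(rep(0, length(times)))
  counts <- numeric(length(times))
  for (id in unique(waves$roi_id)) {
    ev <- waves[waves$roi_id == id, ]
    inwave <- rep(FALSE, length(times))
    for (e in seq_len(nrow(ev)))
      inwave <- inwave | (times >= ev$onset_time[e] & times <= ev$end_time[e])
    counts <- counts + inwave
  }
  counts / n_rois
}

#' Maximum lagged cross-correlation matrix
#'
#' Synchrony between ROI pairs independent of fixed phase shifts: entry
#' `(i, j)` is the maximum over lags `|lag| <= max_lag_s` of the Pearson
#' correlation between the mean-centered traces (fixed full-trace
#' normalization, so lag 0 equals the ordinary Pearson correlation).
#' Zero-variance traces yield `NA` rows/columns and a warning rather than a
#' silent 0. The diagonal is 1.
#'
#' @param traces A `roi_trace_set` (uses the normalized traces) or a
#'   t x K numeric matrix.
#' @param max_lag_s Maximum lag in seconds (default 120, about two typical
#'   wave durations).
#' @param frame_interval Seconds per frame when `traces` is a plain matrix.
#' @return K x K symmetric matrix of maximum correlations.
#' @export
cross_correlation_matrix <- function(traces, max_lag_s = 120,
                                     frame_interval = NULL) {
  if (inherits(traces, "roi_trace_set")) {
    x <- traces$norm; fi <- traces$frame_interval
  } else {
    x <- traces; fi <- if (is.null(frame_interval)) 1 else frame_interval
  }
  n <- nrow(x); K <- ncol(x)
  if (K < 2) stop("need at least 2 ROI traces", call. = FALSE)
  cen <- sweep(x, 2, colMeans(x))
  sds <- sqrt(colSums(cen^2))
  degen <- sds == 0
  if (any(degen)) warning(sprintf("%d zero-variance trace(s); entries set NA",
                                  sum(degen)))
  L <- min(n - 1, floor(max_lag_s / fi))
  best <- matrix(-Inf, K, K)
  for (l in 0:L) {
    a <- cen[1:(n - l), , drop = FALSE]
    b <- cen[(1 + l):n, , drop = FALSE]
    cc <- crossprod(a, b) / tcrossprod(sds, sds)   # corr of i vs lagged j
    best <- pmax(best, cc, t(cc))
  }
  best[degen, ] <- NA; best[, degen] <- NA
  diag(best) <- ifelse(degen, NA, 1)
  best
}

#' Per-pulse entrainment metrics
#'
#' Splits the recording into per-pulse windows (`[on_i, on_{i+1})`, the last
#' window extending to the recording end) and reports, per pulse: waves per
#' ROI, the trapezoidal area under the mean normalized trace normalized to
#' the first pulse (AUC of pulse 1 is 1 by construction), and the response
#' latency mean and SD across ROIs. Also reports the wave probability trace
#' and the median inter-wave interval pooled across ROIs.
#'
#' @param waves A `wave_table`.
#' @param traces The `roi_trace_set` the waves came from.
#' @param protocol A [stimulus_protocol()] with at least one pulse.
#' @param latency_window_s Cap on per-pulse response latency search (default:
#'   the window length).
#' @return A `pulse_metrics` list: `per_pulse` data frame (`pulse`, `on_s`,
#'   `waves_per_roi`, `auc_norm`, `latency_mean_s`, `latency_sd_s`,
#'   `n_responding`), `probability` (vector over `traces$time`),
#'   `median_interval_s`, and `n_rois`.
#' @export
pulse_metrics <- function(waves, traces, protocol, latency_window_s = NULL) {
  P <- nrow(protocol)
  if (P < 1) stop("protocol must contain at least one pulse", call. = FALSE)
  tmax <- max(traces$time) + traces$frame_interval
  bounds <- c(protocol$on_s, tmax)
  K <- length(traces$roi_id)
  mean_trace <- rowMeans(traces$norm)
  per <- lapply(seq_len(P), function(p) {
    w0 <- bounds[p]; w1 <- bounds[p + 1]
    inw <- waves$peak_time >= w0 & waves$peak_time < w1
    sel <- traces$time >= w0 & traces$time < w1
    auc <- trapz(traces$time[sel], mean_trace[sel])
    lat_w <- if (is.null(latency_window_s)) w1 - w0 else latency_window_s
    lats <- vapply(traces$roi_id, function(id)
      response_latency(waves[waves$roi_id == id, ], w0, lat_w), 0)
    lats <- lats[!is.na(lats)]
    data.frame(pulse = p, on_s = w0,
               waves_per_roi = sum(inw) / K,
               auc = auc,
               latency_mean_s = if (length(lats)) mean(lats) else NA_real_,
               latency_sd_s = if (length(lats) >= 2) sd(lats) else NA_real_,
               n_responding = length(lats))
  })
  per <- do.call(rbind, per)
  per$auc_norm <- per$auc / per$auc[1]
  iv <- wave_intervals(waves)
  structure(list(per_pulse = per,
                 probability = wave_probability(waves, K, traces$time),
                 median_interval_s = if (nrow(iv$intervals))
                   median(iv$intervals$interval_s) else NA_real_,
                 n_rois = K),
            class = "pulse_metrics")
}

trapz <- function(x, y) {
  if (length(x) < 2) return(0)
  sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
}

#' @export
print.pulse_metrics <- function(x, ...) {
  cat(sprintf("<pulse_metrics> %d pulses, %d ROIs, median interval %.1f s\n",
              nrow(x$per_pulse), x$n_rois, x$median_interval_s))
  print(x$per_pulse, row.names = FALSE)
  invisible(x)
}
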