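#' Wave program parameters
#'
#' Defaults reproduce the statistical structure of chitin-elicited calcium
#' dynamics in protonemal colonies: per-ROI characteristic inter-wave
#' intervals around 159.7 s with an across-ROI CV of 45.4% and a within-ROI
#' jitter CV of 19.2%; Gaussian wave shapes parameterized by FW10 duration
#' (mean 77 s, range 30-120 s, `sigma = FW10 / (2*sqrt(2*ln 10))`);
#' stimulus-locked first waves at onset plus a latency whose mean drifts
#' linearly across pulses from 25 s (first) to 64 s (last) with 24 s jitter
#' SD; evoked amplitudes ~2.7 dF/F0 versus ~0.7 for spontaneous waves; fast
#' spontaneous oscillations in CA* apical tip regions with median interval
#' 85.5 s before stimulation; and a 30 s refractory period separating any
#' two waves in one ROI.
#'
#' @param baseline_f0_mean,baseline_f0_sd Per-ROI baseline fluorescence
#'   (arbitrary camera units).
#' @param amp_mean,amp_sd Evoked wave amplitude (dF/F0).
#' @param spont_amp_mean,spont_amp_sd Spontaneous wave amplitude (dF/F0).
#' @param fw10_mean,fw10_sd,fw10_min,fw10_max Wave FW10 duration (s).
#' @param interval_mean Mean per-ROI characteristic interval (s).
#' @param interval_cv_across Across-ROI CV of characteristic intervals.
#' @param interval_cv_within Within-ROI interval jitter CV.
#' @param ca_star_interval_median Median CA* spontaneous interval (s).
#' @param ca_star_interval_sdlog Log-SD of CA* intervals.
#' @param spont_rate_per_30min Spontaneous wave rate per ROI outside
#'   stimulation (long-adapted daytime colonies are nearly silent).
#' @param latency_mean_start_s,latency_mean_end_s Mean response latency at
#'   the first and last pulse (linear drift in between).
#' @param latency_sd_s Latency jitter SD (s).
#' @param latency_min_s Lower clip on latencies (s).
#' @param refractory_s Minimum separation of waves within one ROI (s).
#' @param responsive_frac Fraction of ROIs responding to stimulation.
#' @param baseline_elev,baseline_tau_s Relative baseline elevation at
#'   stimulus onset and its decay time constant (s).
#' @return A `wave_params` list.
#' @export
wave_params <- function(baseline_f0_mean = 300, baseline_f0_sd = 60,
                        amp_mean = 2.7, amp_sd = 0.6,
                        spont_amp_mean = 0.7, spont_amp_sd = 0.2,
                        fw10_mean = 77, fw10_sd = 15,
                        fw10_min = 30, fw10_max = 120,
                        interval_mean = 159.7,
                        interval_cv_across = 0.454,
                        interval_cv_within = 0.192,
                        ca_star_interval_median = 85.5,
                        ca_star_interval_sdlog = 0.6,
                        spont_rate_per_30min = 0.2,
                        latency_mean_start_s = 25,
                        latency_mean_end_s = 64,
                        latency_sd_s = 24,
                        latency_min_s = 5,
                        refractory_s = 30,
                        responsive_frac = 1,
                        baseline_elev = 0.25,
                        baseline_tau_s = 600) {
  p <- as.list(environment())
  structure(p, class = "wave_params")
}

# sigma of a Gaussian wave with the given full width at 10% of peak
fw10_to_sigma <- function(fw10) fw10 / (2 * sqrt(2 * log(10)))

#' Schedule calcium waves for a colony
#'
#' Draws, per ground-truth region (ROI), a baseline F0 and a characteristic
#' oscillation interval, then lays out wave events: a stimulus-locked first
#' wave per pulse whose 10% rising crossing (the initiation, which is how
#' response latency is measured) falls at onset plus a drifting, jittered
#' latency; continued
#' oscillation at the ROI's characteristic interval (with within-ROI jitter)
#' while the stimulus remains on; rare spontaneous waves outside stimulation;
#' and fast spontaneous oscillations in CA* apical tip regions before the
#' first stimulus. Waves violating the refractory period are dropped
#' (earliest kept).
#'
#' @param geometry A `colony_geometry` from [build_geometry()].
#' @param protocol A [stimulus_protocol()]; may contain zero pulses.
#' @param params A [wave_params()].
#' @param seed Integer seed.
#' @return A `wave_program`: list with `waves` (data frame: region_id,
#'   peak_time, amplitude, sigma, fw10, stimulated, pulse), `f0` (per-region
#'   baseline vector), `params`, and `protocol`.
#' @export
schedule_waves <- function(geometry, protocol, params = wave_params(),
                           seed = 0) {
  if (!inherits(geometry, "colony_geometry") || nrow(geometry$regions) == 0)
    stop("`geometry` must be a non-empty colony_geometry", call. = FALSE)
  p <- params
  regions <- geometry$regions
  R <- nrow(regions)
  dur <- protocol_duration(protocol)
  P <- nrow(protocol)
  with_seed(seed, {
    f0 <- pmax(100, rnorm(R, p$baseline_f0_mean, p$baseline_f0_sd))
    sdlog_a <- sqrt(log(1 + p$interval_cv_across^2))
    char_int <- clamp(rlnorm(R, log(p$interval_mean) - sdlog_a^2 / 2, sdlog_a),
                      60, 320)
    responsive <- runif(R) < p$responsive_frac
    lat_mean <- if (P >= 2)
      p$latency_mean_start_s +
        (p$latency_mean_end_s - p$latency_mean_start_s) * (seq_len(P) - 1) / (P - 1)
    else rep(p$latency_mean_start_s, P)
    draw_fw10 <- function(n) clamp(rnorm(n, p$fw10_mean, p$fw10_sd),
                                   p$fw10_min, p$fw10_max)
    # response latency is defined at the 10% rising crossing, which for a
    # Gaussian wave precedes the peak by sigma * sqrt(2 ln 10)
    onset_lead <- function(fw10) fw10_to_sigma(fw10) * sqrt(2 * log(10))
    waves <- vector("list", R)
    for (r in seq_len(R)) {
      times <- numeric(0); stim <- logical(0); pulse <- integer(0)
      fw10s <- numeric(0)
      if (responsive[r]) {
        for (pi in seq_len(P)) {
          on <- protocol$on_s[pi]; off <- protocol$off_s[pi]
          lat <- max(p$latency_min_s, rnorm(1, lat_mean[pi], p$latency_sd_s))
          f1 <- draw_fw10(1)
          t1 <- on + lat + onset_lead(f1)        # 10% onset at on + latency
          if (t1 <= dur) {
            times <- c(times, t1); stim <- c(stim, TRUE)
            pulse <- c(pulse, pi); fw10s <- c(fw10s, f1)
          }
          tt <- t1
          repeat {
            gap <- max(p$refractory_s,
                       char_int[r] * (1 + rnorm(1, 0, p$interval_cv_within)))
            tt <- tt + gap
            if (tt > off || tt > dur) break
            times <- c(times, tt); stim <- c(stim, TRUE)
            pulse <- c(pulse, pi); fw10s <- c(fw10s, draw_fw10(1))
          }
        }
      }
      # spontaneous waves outside stimulation
      is_tip <- regions$region_type[r] == "CA*"
      first_on <- if (P >= 1) protocol$on_s[1] else dur
      if (is_tip && first_on > 0) {
        tt <- runif(1, 0, p$ca_star_interval_median)
        while (tt < first_on) {
          times <- c(times, tt); stim <- c(stim, FALSE)
          pulse <- c(pulse, NA); fw10s <- c(fw10s, draw_fw10(1))
          tt <- tt + max(p$refractory_s,
                         rlnorm(1, log(p$ca_star_interval_median),
                                p$ca_star_interval_sdlog))
        }
      } else if (p$spont_rate_per_30min > 0) {
        off_time <- dur - sum(protocol$off_s - protocol$on_s)
        n_sp <- rpois(1, p$spont_rate_per_30min * off_time / 1800)
        if (n_sp > 0) {
          cand <- runif(n_sp, 0, dur)
          cand <- cand[!stimulus_state(protocol, cand)]
          times <- c(times, cand)
          stim <- c(stim, rep(FALSE, length(cand)))
          pulse <- c(pulse, rep(NA, length(cand)))
          fw10s <- c(fw10s, draw_fw10(length(cand)))
        }
      }
      if (!length(times)) { waves[[r]] <- NULL; next }
      o <- order(times)
      times <- times[o]; stim <- stim[o]; pulse <- pulse[o]; fw10s <- fw10s[o]
      keep <- enforce_refractory(times, p$refractory_s)
      times <- times[keep]; stim <- stim[keep]; pulse <- pulse[keep]
      fw10s <- fw10s[keep]
      n <- length(times)
      amp <- ifelse(stim,
                    pmax(0.3, rnorm(n, p$amp_mean, p$amp_sd)),
                    pmax(0.2, rnorm(n, p$spont_amp_mean, p$spont_amp_sd)))
      waves[[r]] <- data.frame(region_id = regions$region_id[r],
                               peak_time = times, amplitude = amp,
                               sigma = fw10_to_sigma(fw10s), fw10 = fw10s,
                               stimulated = stim, pulse = pulse)
    }
    waves <- do.call(rbind, waves)
    if (is.null(waves))
      waves <- data.frame(region_id = integer(0), peak_time = numeric(0),
                          amplitude = numeric(0), sigma = numeric(0),
                          fw10 = numeric(0), stimulated = logical(0),
                          pulse = integer(0))
    rownames(waves) <- NULL
    structure(list(waves = waves, f0 = f0, params = p, protocol = protocol),
              class = "wave_program")
  })
}

# keep earliest wave of any pair closer than the refractory period
enforce_refractory <- function(times, refractory) {
  keep <- logical(length(times))
  last <- -Inf
  for (i in seq_along(times)) {
    if (times[i] - last >= refractory) { keep[i] <- TRUE; last <- times[i] }
  }
  keep
}

#' @export
print.wave_program <- function(x, ...) {
  cat(sprintf("<wave_program> %d waves over %d regions (%d stimulated)\n",
              nrow(x$waves), length(x$f0), sum(x$waves$stimulated)))
  invisible(x)
}

#' Programmed (noise-free) normalized trace of one region
#'
#' The forward model each ROI trace is rendered from: a sum of Gaussian
#' waves over an elevated-baseline term, in dF/F0 units.
#'
#' @param program A `wave_program`.
#' @param region_id Region id.
#' @param times Evaluation times (s).
#' @return Numeric vector: `sum_w A_w exp(-(t - t_w)^2 / (2 sigma_w^2))`
#'   plus the baseline elevation term.
#' @export
programmed_trace <- function(program, region_id, times) {
  w <- program$waves[program$waves$region_id == region_id, ]
  out <- rep(0, length(times))
  for (i in seq_len(nrow(w)))
    out <- out + w$amplitude[i] * exp(-(times - w$peak_time[i])^2 / (2 * w$sigma[i]^2))
  p <- program$params
  if (nrow(program$protocol) >= 1 && p$baseline_elev > 0) {
    t_on <- program$protocol$on_s[1]
    out <- out + ifelse(times >= t_on,
                        p$baseline_elev * exp(-(times - t_on) / p$baseline_tau_s), 0)
  }
  out
}
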