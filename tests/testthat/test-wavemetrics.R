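test_that("flat traces with tiny noise yield no waves", {
  set.seed(5)
  tr <- rnorm(600, 0, 0.005)
  expect_equal(nrow(detect_waves(tr)), 0)
  expect_equal(nrow(detect_waves(rep(0.3, 100))), 0)
})

test_that("a noiseless Gaussian wave matches its closed-form shape metrics", {
  t <- 0:599
  sigma <- 14
  tr <- 2 * exp(-(t - 300)^2 / (2 * sigma^2))
  w <- detect_waves(tr, frame_interval = 1)
  expect_equal(nrow(w), 1)
  expect_equal(w$peak_time, 300)
  expect_equal(w$peak_value, 2, tolerance = 1e-6)
  expect_equal(w$prominence, 2, tolerance = 1e-6)
  # FW10 = 2 sigma sqrt(2 ln 10) = 4.29193 sigma, within one frame
  expect_lt(abs(w$fw10_duration - 2 * sigma * sqrt(2 * log(10))), 1)
  # rise = fall = sigma (sqrt(2 ln 10) - sqrt(2 ln(10/9))) = 1.68692 sigma
  rise_cf <- sigma * (sqrt(2 * log(10)) - sqrt(2 * log(10 / 9)))
  expect_lt(abs(w$rise_time - rise_cf), 1)
  expect_lt(abs(w$fall_time - rise_cf), 1)
  expect_equal(w$rise_time, w$fall_time, tolerance = 1e-6)  # symmetry
  expect_equal(w$fw10_duration, w$end_time - w$onset_time)
  # invariant orderings
  expect_lt(w$onset_time, w$peak_time)
  expect_lt(w$peak_time, w$end_time)
  expect_lte(w$rise_time, w$peak_time - w$onset_time + 1e-9)
})

test_that("closed forms hold across sigma values (parameterized)", {
  t <- 0:999
  for (sigma in c(7, 10, 20, 28)) {
    tr <- 1.5 * exp(-(t - 500)^2 / (2 * sigma^2))
    w <- detect_waves(tr)
    expect_lt(abs(w$fw10_duration - 4.29193 * sigma), 1)
    expect_lt(abs(w$rise_time - 1.68692 * sigma), 1)
    expect_lt(abs(w$rise_time - w$fall_time), 1)
  }
})

test_that("two separated Gaussians give two waves at the right interval", {
  t <- 0:499
  tr <- 2 * exp(-(t - 100)^2 / 200) + 2 * exp(-(t - 300)^2 / 200)
  w <- detect_waves(tr)
  expect_equal(nrow(w), 2)
  expect_equal(diff(w$peak_time), 200)
  iv <- wave_intervals(w)
  expect_equal(iv$intervals$interval_s, 200)
})

test_that("sub-threshold peaks are rejected by the MAD prominence rule", {
  set.seed(8)
  t <- 0:899
  # strong oscillation plus a tiny bump well below 0.35 * MAD
  tr <- 2 * (exp(-(t - 200)^2 / 450) + exp(-(t - 450)^2 / 450) +
             exp(-(t - 700)^2 / 450)) + 0.02 * exp(-(t - 330)^2 / 80)
  w <- detect_waves(tr)
  expect_equal(nrow(w), 3)
})

test_that("peaks closer than the merge window collapse to the higher one", {
  t <- 0:299
  tr <- 2 * exp(-(t - 150)^2 / (2 * 9)) + 1.4 * exp(-(t - 155)^2 / (2 * 9))
  w <- detect_waves(tr, merge_s = 10)
  expect_equal(nrow(w), 1)
  expect_equal(w$peak_time, 150, tolerance = 2)
})

test_that("interval statistics match hand-computed values", {
  ev <- data.frame(roi_id = 1, peak_time = c(0, 150, 300))
  iv <- wave_intervals(ev)
  expect_equal(iv$intervals$interval_s, c(150, 150))
  expect_equal(iv$per_roi$cv_pct, 0)
  expect_equal(iv$per_roi$freq_per_min, 60 / 150)
  ev2 <- data.frame(roi_id = 1, peak_time = c(0, 100, 300))
  iv2 <- wave_intervals(ev2)
  expect_equal(iv2$per_roi$mean_interval_s, 150)
  expect_equal(iv2$per_roi$cv_pct, 100 * sd(c(100, 200)) / 150)  # ~47.1%
  # too few events: empty results, not errors
  iv3 <- wave_intervals(data.frame(roi_id = 1, peak_time = 5))
  expect_equal(nrow(iv3$intervals), 0)
  expect_true(is.na(iv3$per_roi$cv_pct))
})

test_that("response latency uses the 10% rising crossing after onset", {
  t <- 0:299
  sigma <- 10
  tr <- 1.5 * exp(-(t - 130)^2 / (2 * sigma^2))   # peak 30 s after onset 100
  ev <- detect_waves(tr)
  lat <- response_latency(ev, onset_s = 100)
  expect_equal(lat, 30 - sigma * sqrt(2 * log(10)), tolerance = 0.2)
  # wave entirely before the onset is a missing response
  expect_true(is.na(response_latency(ev, onset_s = 200)))
})

test_that("wave probability is the in-FW10 fraction of ROIs", {
  ev <- data.frame(roi_id = c(1, 2), onset_time = c(100, 100),
                   end_time = c(160, 160), peak_time = c(130, 130))
  p <- wave_probability(ev, n_rois = 2, times = c(50, 130, 200))
  expect_equal(p, c(0, 1, 0))
  # 2 of 4 ROIs in-wave gives 0.5
  p2 <- wave_probability(ev, n_rois = 4, times = 130)
  expect_equal(p2, 0.5)
  expect_equal(wave_probability(ev[0, ], 4, times = 1:5), rep(0, 5))
  # integral of a synchronized wave's probability ~ mean FW10
  times <- 0:300
  expect_equal(sum(wave_probability(ev, 2, times)), 61, tolerance = 2)
})

test_that("max cross-correlation finds shifted copies and stays low for noise", {
  set.seed(12)
  n <- 1200
  base <- as.numeric(stats::filter(rnorm(n + 30), rep(1, 20), sides = 1))[-(1:30)]
  x <- cbind(base, c(base[31:n], base[1:30]), rnorm(n))
  cc <- suppressWarnings(cross_correlation_matrix(x, max_lag_s = 60,
                                                  frame_interval = 1))
  expect_equal(diag(cc), rep(1, 3))
  expect_gt(cc[1, 2], 0.95)                       # 30 s shifted copy
  expect_equal(cc, t(cc))
  # independent white noise traces decorrelate
  set.seed(13)
  y <- matrix(rnorm(3600 * 2), 3600, 2)
  cc2 <- cross_correlation_matrix(y, max_lag_s = 120)
  expect_lt(abs(cc2[1, 2]), 0.2)
  # zero-variance trace flags NA instead of silent zero
  z <- cbind(rnorm(100), rep(1, 100))
  expect_warning(cc3 <- cross_correlation_matrix(z, 10), "zero-variance")
  expect_true(is.na(cc3[1, 2]))
})

test_that("pulse metrics normalize AUC to pulse 1 and count consistently", {
  t <- 0:719
  resp <- function(t0, a) a * exp(-(t - t0)^2 / (2 * 12^2))
  tr <- resp(60, 2) + resp(300, 1) + resp(540, 2)   # pulse 2 at half scale
  traces <- structure(list(time = t, f = cbind(tr + 1), norm = cbind(tr),
                           f0 = 1, area_px2 = 20, centroid = matrix(0, 1, 2),
                           roi_id = 1L, frame_interval = 1),
                      class = "roi_trace_set")
  prot <- stimulus_protocol(c(30, 270, 510), c(90, 330, 570), 720)
  waves <- detect_all_waves(traces)
  pm <- pulse_metrics(waves, traces, prot)
  expect_equal(pm$per_pulse$auc_norm[1], 1)
  expect_equal(pm$per_pulse$auc_norm[2], 0.5, tolerance = 0.05)
  expect_equal(pm$per_pulse$auc_norm[3], 1, tolerance = 0.05)
  # per-pulse wave counts sum to the total
  expect_equal(sum(pm$per_pulse$waves_per_roi) * pm$n_rois, nrow(waves))
  expect_true(all(pm$probability >= 0 & pm$probability <= 1))
  expect_equal(pm$per_pulse$latency_mean_s,
               rep(30 - 12 * sqrt(2 * log(10)), 3), tolerance = 0.3)
})

test_that("wave snippets are 121 samples centered and peak-normalized", {
  sc <- small_colony()
  tr <- extract_traces(sc$stack, sc$ground_truth$label_map)
  waves <- detect_all_waves(tr, window_s = 60)
  snip <- attr(waves, "snippets")
  expect_equal(ncol(snip), 121)
  expect_equal(nrow(snip), nrow(waves))
  expect_equal(unname(snip[, 61]), rep(1, nrow(waves)))  # peak-normalized
})

test_that("detector recovers the programmed schedule on noisy colonies", {
  sc <- small_colony()
  tr <- extract_traces(sc$stack, sc$ground_truth$label_map)
  waves <- detect_all_waves(tr)
  st <- wave_match_stats(waves, sc$program, window_s = 15)
  expect_gte(st$recall, 0.9)
  expect_gte(st$precision, 0.9)
})

test_that("recovered latencies drift upward across repeated pulses", {
  g <- build_geometry(seed = 31, n_filaments = 3, cells_per_filament = 3)
  prot <- pulse_train(5, 60, 300, first_on_s = 120, duration_s = 1700)
  lat <- matrix(NA_real_, 12, 5)
  for (s in seq_len(12)) {
    prog <- schedule_waves(g, prot, wave_params(latency_sd_s = 8,
                                                spont_rate_per_30min = 0),
                           seed = 400 + s)
    for (p in 1:5) {
      w <- prog$waves[!is.na(prog$waves$pulse) & prog$waves$pulse == p, ]
      lat[s, p] <- mean(w$peak_time - prot$on_s[p])
    }
  }
  ml <- colMeans(lat)
  expect_true(all(diff(ml) > 0))                  # 25 -> 64 s linear drift
  expect_equal(ml[1] - ml[1], 0)
  expect_gt(ml[5] - ml[1], 20)
})

test_that("within-ROI interval CV is below the across-ROI CV on recovery", {
  # long continuous exposure: every ROI oscillates at its own characteristic
  # interval, the condition under which per-cell regularity shows up
  g <- build_geometry(seed = 71, n_filaments = 4, cells_per_filament = 4)
  prot <- stimulus_protocol(0, 1800, 1800)
  prog <- schedule_waves(g, prot, wave_params(), seed = 72)
  times <- 0:1799
  set.seed(73)
  norm <- vapply(g$regions$region_id, function(rid)
    programmed_trace(prog, rid, times) + rnorm(length(times), 0, 0.02),
    numeric(length(times)))
  tr <- structure(list(time = times, f = norm + 1, norm = norm,
                       f0 = rep(1, ncol(norm)),
                       area_px2 = rep(100, ncol(norm)),
                       centroid = matrix(0, ncol(norm), 2),
                       roi_id = g$regions$region_id, frame_interval = 1),
                  class = "roi_trace_set")
  waves <- detect_all_waves(tr)
  iv <- wave_intervals(waves)
  per <- iv$per_roi[!is.na(iv$per_roi$cv_pct) & iv$per_roi$n_waves >= 5, ]
  expect_gt(nrow(per), 10)
  within <- mean(per$cv_pct)
  across <- 100 * sd(iv$intervals$interval_s) / mean(iv$intervals$interval_s)
  expect_lt(within, across)
})
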