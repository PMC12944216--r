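test_that("minimal geometry yields one filament, one tip cell, a region", {
  g <- build_geometry(seed = 1, n_filaments = 1, cells_per_filament = 1,
                      branch_prob = 0)
  expect_length(g$filaments, 1)
  expect_equal(nrow(g$cells), 1)
  expect_true(g$cells$cell_type %in% c("CA", "CH"))
  expect_gte(nrow(g$regions), 1)
})

test_that("geometry generation is deterministic and validates inputs", {
  g1 <- build_geometry(seed = 1, n_filaments = 2, cells_per_filament = 5,
                       branch_prob = 0.3)
  g2 <- build_geometry(seed = 1, n_filaments = 2, cells_per_filament = 5,
                       branch_prob = 0.3)
  expect_identical(g1, g2)
  expect_gte(nrow(g1$cells), 10)                  # 10 main cells + branches
  expect_error(build_geometry(seed = 1, n_filaments = 0,
                              cells_per_filament = 1), "integer >= 1")
})

test_that("every CA tip cell carries exactly one apical CA* region", {
  g <- build_geometry(seed = 7, n_filaments = 3, cells_per_filament = 4)
  ca_tips <- g$cells$cell_id[g$cells$cell_type == "CA"]
  for (cid in ca_tips) {
    regs <- g$regions[g$regions$cell_id == cid, ]
    stars <- regs[regs$region_type == "CA*", ]
    expect_equal(nrow(stars), 1)
    # apical end: the CA* region ends at the cell's outer boundary
    expect_equal(stars$s1_um, g$cells$s1_um[g$cells$cell_id == cid])
    expect_equal(stars$s1_um, max(regs$s1_um))
  }
  # and CA* appears nowhere else
  other <- g$regions[!(g$regions$cell_id %in% ca_tips), ]
  expect_false(any(other$region_type == "CA*"))
})

test_that("cells are contiguous within filaments and regions nest in cells", {
  g <- build_geometry(seed = 13, n_filaments = 4, cells_per_filament = 5,
                      branch_prob = 0.3)
  for (fid in unique(g$cells$filament_id)) {
    ce <- g$cells[g$cells$filament_id == fid, ]
    ce <- ce[order(ce$s0_um), ]
    expect_equal(ce$s0_um[1], 0)
    if (nrow(ce) > 1)
      expect_equal(ce$s0_um[-1], ce$s1_um[-nrow(ce)])
  }
  for (i in seq_len(nrow(g$regions))) {
    r <- g$regions[i, ]
    ce <- g$cells[g$cells$cell_id == r$cell_id, ]
    expect_gte(r$s0_um, ce$s0_um - 1e-9)
    expect_lte(r$s1_um, ce$s1_um + 1e-9)
  }
})

test_that("silent programs produce empty schedules", {
  g <- build_geometry(seed = 2, n_filaments = 2, cells_per_filament = 3)
  prot <- stimulus_protocol(numeric(0), numeric(0), 600)
  prog <- schedule_waves(g, prot, wave_params(spont_rate_per_30min = 0,
                                              ca_star_interval_median = 1e9),
                         seed = 5)
  expect_equal(nrow(prog$waves), 0)
})

test_that("pulse trains evoke waves in every pulse window with drifting latency", {
  g <- build_geometry(seed = 3, n_filaments = 3, cells_per_filament = 3)
  prot <- pulse_train(10, 60, 240, first_on_s = 120, duration_s = 2640)
  lat_by_pulse <- matrix(NA_real_, 40, 10)
  cover <- TRUE
  for (s in 1:40) {
    prog <- schedule_waves(g, prot,
                           wave_params(spont_rate_per_30min = 0,
                                       ca_star_interval_median = 1e9),
                           seed = s)
    w <- prog$waves[prog$waves$stimulated, ]
    for (p in 1:10) {
      wp <- w[!is.na(w$pulse) & w$pulse == p, ]
      # every responsive region initiates a wave for every pulse
      if (length(unique(wp$region_id)) < nrow(g$regions)) cover <- FALSE
      lat_by_pulse[s, p] <- mean(wp$peak_time - prot$on_s[p])
    }
  }
  expect_true(cover)
  mean_lat <- colMeans(lat_by_pulse)
  # mean latencies drift upward across pulses (monotone in expectation)
  expect_gt(mean_lat[10], mean_lat[1])
  expect_true(all(diff(mean_lat) > -5))           # nondecreasing up to noise
})

test_that("within-ROI interval CV matches the programmed jitter", {
  g <- build_geometry(seed = 4, n_filaments = 3, cells_per_filament = 4)
  prot <- stimulus_protocol(0, 1800, 1800)        # one 30 min exposure
  prog <- schedule_waves(g, prot,
                         wave_params(interval_mean = 150,
                                     interval_cv_across = 0,
                                     interval_cv_within = 0.19,
                                     latency_sd_s = 5,
                                     spont_rate_per_30min = 0),
                         seed = 9)
  cvs <- c()
  for (rid in unique(prog$waves$region_id)) {
    pt <- sort(prog$waves$peak_time[prog$waves$region_id == rid])
    if (length(pt) >= 9) {
      iv <- diff(pt)
      cvs <- c(cvs, sd(iv) / mean(iv))
    }
  }
  expect_gt(length(cvs), 5)
  expect_true(all(cvs > 0.08 & cvs < 0.32))
})

test_that("refractory separation holds for every scheduled pair", {
  g <- build_geometry(seed = 5, n_filaments = 4, cells_per_filament = 4)
  prot <- pulse_train(5, 300, 600, first_on_s = 300, duration_s = 3300)
  prog <- schedule_waves(g, prot, wave_params(), seed = 77)
  for (rid in unique(prog$waves$region_id)) {
    pt <- sort(prog$waves$peak_time[prog$waves$region_id == rid])
    if (length(pt) > 1)
      expect_gte(min(diff(pt)), prog$params$refractory_s - 1e-9)
  }
})

test_that("noise-free static scenes render identically in every frame", {
  g <- build_geometry(seed = 6, n_filaments = 2, cells_per_filament = 2)
  prot <- stimulus_protocol(numeric(0), numeric(0), 20)
  prog <- schedule_waves(g, prot, wave_params(spont_rate_per_30min = 0,
                                              ca_star_interval_median = 1e9),
                         seed = 1)
  acq <- acquisition_model(poisson_gain = 0, read_noise_sd = 0)
  r <- render_stack(g, prog, acq, duration_s = 20, seed = 1)
  ref <- r$stack$data[, , 1]
  for (i in 2:20) expect_identical(r$stack$data[, , i], ref)
  expect_equal(max(apply(r$stack$data, c(1, 2), sd)), 0)
})

test_that("a programmed wave renders at its closed-form amplitude and time", {
  sc <- small_colony_clean()
  tr <- extract_traces(sc$stack, sc$ground_truth$label_map,
                       baseline_percentile = 0)
  prog <- sc$program
  # pick the region whose largest wave is well separated from others
  rid <- prog$waves$region_id[which.max(prog$waves$amplitude)]
  w <- prog$waves[prog$waves$region_id == rid, ]
  big <- w[which.max(w$amplitude), ]
  j <- match(rid, tr$roi_id)
  t_idx <- round(big$peak_time) + 1
  expected <- programmed_trace(prog, rid, big$peak_time)
  expect_lt(abs(tr$norm[t_idx, j] - expected) / expected, 0.1)
  # trace peaks within 2 s of the programmed peak in a +/- 40 s window
  win <- max(1, t_idx - 40):min(nrow(tr$norm), t_idx + 40)
  expect_lte(abs(which.max(tr$norm[win, j]) + win[1] - 1 - t_idx), 2)
})

test_that("noise-free ROI-average traces match the programmed traces", {
  sc <- small_colony_clean()
  tr <- extract_traces(sc$stack, sc$ground_truth$label_map,
                       baseline_percentile = 0)
  times <- tr$time
  err <- vapply(seq_along(tr$roi_id), function(j) {
    want <- programmed_trace(sc$program, tr$roi_id[j], times)
    max(abs(tr$norm[, j] - want))
  }, 0)
  expect_lt(median(err), 0.15)                    # PSF/taper bleed tolerance
})

test_that("programmed waves are time-symmetric on the noiseless trace", {
  sc <- small_colony_clean()
  tr <- extract_traces(sc$stack, sc$ground_truth$label_map,
                       baseline_percentile = 0)
  waves <- detect_all_waves(tr)
  # restrict to isolated waves: overlapping flanks legitimately break the
  # per-wave symmetry of the summed trace
  iso <- vapply(seq_len(nrow(waves)), function(i) {
    same <- waves[waves$roi_id == waves$roi_id[i], ]
    gaps <- abs(same$peak_time - waves$peak_time[i])
    all(gaps[gaps > 0] > 1.5 * waves$fw10_duration[i]) ||
      nrow(same) == 1
  }, TRUE)
  ok <- iso & !waves$truncated_left & !waves$truncated_right
  expect_gt(sum(ok), 10)
  asym <- abs(waves$rise_time - waves$fall_time)[ok]
  expect_lt(median(asym), 2)
  expect_gt(mean(asym < 5), 0.8)
})

test_that("ground-truth label map and rendered footprint coincide", {
  sc <- small_colony_clean()
  lab <- sc$ground_truth$label_map$labels
  first <- sc$stack$data[, , 1]
  lit <- first > 1                                # above-background pixels
  # footprint pixels are exactly the labeled pixels (up to PSF bleed ring)
  expect_gt(sum(lit & lab > 0) / sum(lab > 0), 0.99)
})

test_that("rendering is bit-identical under a fixed seed", {
  g <- build_geometry(seed = 8, n_filaments = 2, cells_per_filament = 2)
  prot <- stimulus_protocol(10, 50, 60)
  prog <- schedule_waves(g, prot, wave_params(), seed = 2)
  r1 <- render_stack(g, prog, acquisition_model(), duration_s = 60, seed = 3)
  r2 <- render_stack(g, prog, acquisition_model(), duration_s = 60, seed = 3)
  expect_identical(r1$stack$data, r2$stack$data)
  expect_identical(r1$ground_truth$label_map$labels,
                   r2$ground_truth$label_map$labels)
})

test_that("fixed-size frames reject oversized colonies naming a filament", {
  g <- build_geometry(seed = 9, n_filaments = 4, cells_per_filament = 4)
  prot <- stimulus_protocol(numeric(0), numeric(0), 10)
  prog <- schedule_waves(g, prot, wave_params(spont_rate_per_30min = 0,
                                              ca_star_interval_median = 1e9),
                         seed = 1)
  acq <- acquisition_model(frame_px = c(20, 20))
  expect_error(render_stack(g, prog, acq, duration_s = 10, seed = 1),
               "exceeds.*filament")
})

test_that("simulate_colony writes the declared artifact set", {
  out <- file.path(tempdir(), "simout")
  res <- simulate_colony(seed = 30, n_filaments = 2, cells_per_filament = 2,
                         protocol = stimulus_protocol(30, 90, 120),
                         out_dir = out)
  expect_true(all(file.exists(file.path(out,
    c("stack.tif", "labels.tif", "protocol.json", "ground_truth.json")))))
  back <- read_stack(file.path(out, "stack.tif"))
  expect_identical(dim(back$data), dim(res$stack$data))
  expect_true(all(back$data == res$stack$data))
})
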