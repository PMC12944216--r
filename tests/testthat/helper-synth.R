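# Shared synthetic fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixture_cache[[name]]))
    .fixture_cache[[name]] <- builder()
  .fixture_cache[[name]]
}

# Small noisy colony with a single long stimulus pulse: ~14 true regions,
# 600 s recording. Used by most unit tests.
small_colony <- function() {
  fixture("small", function() {
    geom <- build_geometry(seed = 21, n_filaments = 3, cells_per_filament = 3,
                           branch_prob = 0.15, cell_length_um = 80)
    prot <- stimulus_protocol(150, 450, 600)
    prog <- schedule_waves(geom, prot, wave_params(), seed = 22)
    rend <- render_stack(geom, prog, acquisition_model(), seed = 23)
    c(rend, list(geometry = geom, program = prog, protocol = prot))
  })
}

# Noise-free, background-free render of the same colony (closed-form checks:
# with zero background the ROI-mean dF/F0 equals the programmed trace).
small_colony_clean <- function() {
  fixture("small_clean", function() {
    sc <- small_colony()
    acq <- acquisition_model(poisson_gain = 0, read_noise_sd = 0,
                             background = 0, background_gradient = 0)
    rend <- render_stack(sc$geometry, sc$program, acq, seed = 1)
    c(rend, list(geometry = sc$geometry, program = sc$program,
                 protocol = sc$protocol))
  })
}

conv_small_for_test <- function(arr, kernel) mosswave:::conv_small(arr, kernel)

# Best-match intersection-over-union of every ground-truth region against a
# segmentation label map.
best_match_iou <- function(gt_labels, seg_labels) {
  gids <- sort(unique(gt_labels[gt_labels > 0]))
  vapply(gids, function(gid) {
    gpx <- gt_labels == gid
    cand <- unique(seg_labels[gpx])
    cand <- cand[cand > 0]
    if (!length(cand)) return(0)
    max(vapply(cand, function(sid) {
      spx <- seg_labels == sid
      sum(gpx & spx) / sum(gpx | spx)
    }, 0))
  }, 0)
}

# Precision/recall of detected wave peaks against the programmed schedule,
# matched per ROI within +/- window_s.
wave_match_stats <- function(waves, program, window_s = 15) {
  tp <- 0; n_det <- 0; n_true <- 0
  for (rid in unique(program$waves$region_id)) {
    truth <- program$waves$peak_time[program$waves$region_id == rid]
    det <- waves$peak_time[waves$roi_id == rid]
    n_true <- n_true + length(truth)
    n_det <- n_det + length(det)
    used <- rep(FALSE, length(det))
    for (tt in truth) {
      d <- abs(det - tt)
      d[used] <- Inf
      if (length(d) && min(d) <= window_s) {
        tp <- tp + 1
        used[which.min(d)] <- TRUE
      }
    }
  }
  extra <- setdiff(unique(waves$roi_id), unique(program$waves$region_id))
  n_det <- n_det + sum(waves$roi_id %in% extra)
  list(recall = tp / n_true, precision = tp / n_det)
}
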