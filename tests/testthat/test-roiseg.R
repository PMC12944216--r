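test_that("initial cluster count is floor(area / mean ROI area), clamped", {
  expect_equal(initial_cluster_count(5996, 150), 39)   # worked example
  expect_equal(initial_cluster_count(149, 150), 1)
  expect_equal(initial_cluster_count(300, 150), 2)
  expect_error(initial_cluster_count(0), "integer >= 1")
})

test_that("cosine k-means handles trivial and degenerate cases", {
  set.seed(1)
  X <- matrix(rnorm(40), 8, 5)
  a1 <- cluster_pixels(X, 1, seed = 0)
  expect_true(all(a1 == 1))
  expect_error(cluster_pixels(X, 9, seed = 0), "exceeds")
  # scaled duplicates always co-cluster (cosine scale invariance)
  u <- rnorm(20); v <- rnorm(20)
  X2 <- rbind(u, 5 * u, v, 2 * v, 0.1 * v)
  a2 <- cluster_pixels(X2, 2, seed = 3)
  expect_equal(a2[1], a2[2])
  expect_true(all(a2[3:5] == a2[3]))
  expect_false(a2[1] == a2[3])
})

test_that("cosine k-means finds the exhaustive optimum on 6 pixels", {
  set.seed(3)
  u <- rnorm(30); v <- rnorm(30)
  u <- u / sqrt(sum(u^2)); v <- v / sqrt(sum(v^2))
  stopifnot(1 - sum(u * v) > 0.5)
  X <- rbind(u, 1.2 * u, 0.8 * u, v, 1.5 * v, 0.7 * v)
  a <- cluster_pixels(X, 2, seed = 1)
  expect_equal(a[1:3], rep(a[1], 3))
  expect_equal(a[4:6], rep(a[4], 3))
  expect_false(a[1] == a[4])
  # objective equals brute force over all 2-partitions of 6 items
  part_obj <- function(part) {
    s <- 0
    for (cl in unique(part)) {
      xn <- X[part == cl, , drop = FALSE]
      xn <- xn / sqrt(rowSums(xn^2))
      cen <- colSums(xn); cen <- cen / sqrt(sum(cen^2))
      s <- s + sum(1 - xn %*% cen)
    }
    s
  }
  best <- Inf
  for (m in 1:31) {
    part <- as.integer(intToBits(m))[1:6] + 1L
    if (length(unique(part)) == 2) best <- min(best, part_obj(part))
  }
  expect_equal(attr(a, "objective"), best, tolerance = 1e-9)
})

test_that("clustering is deterministic for a fixed seed", {
  set.seed(9)
  X <- matrix(rnorm(600), 60, 10)
  a1 <- cluster_pixels(X, 5, seed = 11)
  a2 <- cluster_pixels(X, 5, seed = 11)
  expect_identical(as.integer(a1), as.integer(a2))
})

test_that("flat (zero-variance) pixels are assigned by Euclidean fallback", {
  u <- c(rep(1, 10), rep(-1, 10))
  X <- rbind(u, 1.1 * u, -u, -1.2 * u, rep(0, 20))
  a <- cluster_pixels(X, 2, seed = 2)
  expect_length(unique(a[1:2]), 1)
  expect_length(unique(a[3:4]), 1)
  expect_true(a[5] %in% a[1:4])
})

test_that("disconnected clusters split into separate 8-connected ROIs", {
  mask <- matrix(FALSE, 10, 12)
  mask[2:4, 2:4] <- TRUE
  mask[7:9, 8:10] <- TRUE
  assign <- rep(1L, sum(mask))                    # one cluster, two blobs
  lm <- split_disconnected(assign, mask)
  expect_equal(max(lm$labels), 2)
  expect_equal(sort(unique(lm$labels[lm$labels > 0])), 1:2)
  # contiguous cluster stays one ROI
  mask2 <- matrix(FALSE, 6, 6); mask2[2:5, 2:5] <- TRUE
  lm2 <- split_disconnected(rep(1L, 16), mask2)
  expect_equal(max(lm2$labels), 1)
  # diagonal touching counts as connected (8-connectivity)
  mask3 <- matrix(FALSE, 4, 4); mask3[1, 1] <- TRUE; mask3[2, 2] <- TRUE
  lm3 <- split_disconnected(rep(1L, 2), mask3)
  expect_equal(max(lm3$labels), 1)
})

test_that("pruning drops sub-minimum ROIs and renumbers contiguously", {
  lab <- matrix(0L, 12, 12)
  lab[2:3, 2:7] <- 1L                             # 12 px, survives
  lab[6:7, 2:6] <- 2L                             # 10 px (11 after stray) ...
  lab[6, 7] <- 2L                                 # 11 px, pruned
  lab[10:11, 2:9] <- 3L                           # 16 px, survives
  out <- prune_small(roi_label_map(lab), 12)
  expect_equal(max(out$labels), 2)
  expect_equal(sum(out$labels > 0), 12 + 16)
  expect_equal(sort(unique(out$labels[out$labels > 0])), 1:2)
  # identity when nothing is below threshold
  out2 <- prune_small(roi_label_map(lab), 5)
  expect_equal(max(out2$labels), 3)
  expect_error(prune_small(roi_label_map(lab), 1000), "below the minimum")
})

test_that("trace extraction integrates per ROI with a robust baseline", {
  arr <- array(50, c(6, 6, 10))
  lab <- matrix(0L, 6, 6); lab[2:4, 2:4] <- 1L
  tr <- extract_traces(arr, roi_label_map(lab))
  expect_equal(as.numeric(tr$f), rep(50, 10))
  expect_equal(as.numeric(tr$norm), rep(0, 10))
  expect_equal(tr$area_px2, 9)
  # disjoint ROIs have independent traces
  arr2 <- arr
  lab2 <- lab; lab2[6, 6] <- 2L
  t2a <- extract_traces(arr2, roi_label_map(lab2))
  arr2[6, 6, ] <- seq(10, 100, 10)
  t2b <- extract_traces(arr2, roi_label_map(lab2))
  expect_identical(t2a$f[, 1], t2b$f[, 1])
  expect_false(identical(t2a$f[, 2], t2b$f[, 2]))
})

test_that("programmed wave amplitude is recovered from extracted traces", {
  sc <- small_colony_clean()
  tr <- extract_traces(sc$stack, sc$ground_truth$label_map,
                       baseline_percentile = 0)
  w <- sc$program$waves
  rid <- w$region_id[which.max(w$amplitude)]
  big <- w[w$region_id == rid, ][which.max(w$amplitude[w$region_id == rid]), ]
  j <- match(rid, tr$roi_id)
  got <- tr$norm[round(big$peak_time) + 1, j]
  want <- programmed_trace(sc$program, rid, big$peak_time)
  expect_lt(abs(got - want) / want, 0.1)
})

test_that("non-responsive ROIs are excluded at the 100% dF/F0 boundary", {
  t <- 0:599
  mk <- function(amp) 1 + amp * exp(-(t - 350)^2 / (2 * 15^2))
  f <- cbind(mk(0.99), mk(1.01), mk(2.5))
  traces <- structure(list(time = t, f = f,
                           norm = sweep(sweep(f, 2, apply(f, 2, min)), 2,
                                        apply(f, 2, min), "/"),
                           f0 = apply(f, 2, min), area_px2 = rep(20, 3),
                           centroid = matrix(0, 3, 2), roi_id = 1:3,
                           frame_interval = 1),
                      class = "roi_trace_set")
  prot <- stimulus_protocol(300, 500, 600)
  out <- exclude_nonresponsive(traces, prot, threshold = 1.0, window_s = 300)
  expect_equal(out$roi_id, 2:3)
  excl <- attr(out, "exclusions")
  expect_equal(excl$roi_id, 1)
  expect_match(excl$reason, "max dF/F0")
  # fully responsive set: no exclusions
  out2 <- exclude_nonresponsive(traces, prot, threshold = 0.5)
  expect_length(attr(out2, "exclusions")$roi_id, 0)
})

test_that("segmentation recovers ground-truth regions on a noisy colony", {
  sc <- small_colony()
  cm <- build_colony_mask(sc$stack)
  pm <- zscore_pixels(sc$stack$data, cm)
  k <- initial_cluster_count(sum(cm$mask))
  a <- cluster_pixels(pm, k, seed = 4)
  lm <- prune_small(split_disconnected(a, cm))
  # partition property: labels live exactly on mask pixels minus pruned ones
  expect_true(all(cm$mask[lm$labels > 0]))
  ious <- best_match_iou(sc$ground_truth$label_map$labels, lm$labels)
  expect_gte(mean(ious), 0.5)
  expect_gte(mean(ious >= 0.3), 0.8)
})
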