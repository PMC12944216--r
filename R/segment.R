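#' Initial cluster count from colony area
#'
#' The starting `k` for pixel clustering is the total colony pixel area
#' divided by the desired mean ROI area (150 px^2, i.e. 1260 um^2 at
#' 2.9 um/px, an empirical single-cell-scale region size), floored and
#' clamped to at least 1. Example: 5996 colony pixels give k = 39.
#'
#' @param foreground_px Number of colony (foreground) pixels.
#' @param mean_roi_area_px2 Desired mean ROI area in px^2 (default 150).
#' @return Integer cluster count.
#' @export
initial_cluster_count <- function(foreground_px, mean_roi_area_px2 = 150) {
  check_count(foreground_px, "foreground_px", min = 1L)
  check_positive(mean_roi_area_px2, "mean_roi_area_px2")
  max(1L, as.integer(floor(foreground_px / mean_roi_area_px2)))
}

#' k-means clustering of pixel time series with cosine distance
#'
#' Groups Z-scored pixel traces into `k` clusters by k-means under the cosine
#' distance `1 - cos(x, c)`, which matches pixels on the *shape* of their
#' dynamics and is invariant to trace scaling. Each replicate runs batch
#' Lloyd iterations to convergence followed by an online refinement phase in
#' which single pixels are moved (with self-excluded centroid comparison)
#' whenever the move reduces the total within-cluster distance; the best of
#' `replicates` random initializations is returned. Empty clusters are
#' dropped, so the effective number of clusters can shrink. All-zero rows
#' (flat pixels, where cosine is undefined) are held out and assigned at the
#' end to the nearest centroid mean in the Euclidean sense.
#'
#' @param matrix_or_pm A `pixel_matrix` from [zscore_pixels()], or a plain
#'   numeric matrix (rows = pixels, columns = time points).
#' @param k Number of clusters (`1 <= k <=` rows).
#' @param seed Integer seed; fixed seed gives identical assignments.
#' @param replicates Number of random initializations (default 10).
#' @param max_iter Batch iteration cap per replicate (default 100).
#' @param online_passes Cap on online refinement sweeps (default 5).
#' @return Integer vector of cluster ids (1..k at most), one per row, with
#'   attribute `objective` (total within-cluster cosine distance).
#' @export
cluster_pixels <- function(matrix_or_pm, k, seed = 0, replicates = 10,
                           max_iter = 100, online_passes = 5) {
  x <- if (inherits(matrix_or_pm, "pixel_matrix")) matrix_or_pm$z else matrix_or_pm
  n <- nrow(x)
  check_count(k, "k", min = 1L)
  if (k > n) stop(sprintf("k = %d exceeds the %d available pixels", k, n),
                  call. = FALSE)
  nrm <- sqrt(rowSums(x^2))
  live <- which(nrm > 0)
  xn <- x[live, , drop = FALSE] / nrm[live]
  k_eff <- min(k, length(live))
  if (k_eff == 0) return(structure(rep(1L, n), objective = 0))
  best <- NULL
  with_seed(seed, {
    for (rep_i in seq_len(replicates)) {
      res <- kmeans_cosine_once(xn, k_eff, max_iter, online_passes)
      if (is.null(best) || res$objective < best$objective) best <- res
    }
  })
  assign <- integer(n)
  assign[live] <- best$cluster
  if (length(live) < n) {
    # Euclidean fallback for zero-norm rows, against unnormalized centroid means
    cm <- best$centroid_means
    dead <- setdiff(seq_len(n), live)
    d2 <- outer(rep(0, length(dead)), rowSums(cm^2), "+")  # x = 0 vector
    assign[dead] <- max.col(-d2, ties.method = "first")
  }
  structure(assign, objective = best$objective, k_requested = k)
}

# One replicate: batch Lloyd + online phase on unit-normalized rows.
kmeans_cosine_once <- function(xn, k, max_iter, online_passes) {
  n <- nrow(xn)
  init <- sample.int(n, k)
  cen <- xn[init, , drop = FALSE]                      # unit rows
  assign <- integer(n)
  for (it in seq_len(max_iter)) {
    sim <- xn %*% t(cen)
    new_assign <- max.col(sim, ties.method = "first")
    if (it > 1 && all(new_assign == assign)) break
    assign <- new_assign
    keep <- sort(unique(assign))
    if (length(keep) < k) {                            # drop empty clusters
      assign <- match(assign, keep)
      k <- length(keep)
    }
    sums <- rowsum(xn, assign)                         # k x t
    cn <- sqrt(rowSums(sums^2))
    cen <- sums / ifelse(cn > 0, cn, 1)
  }
  sums <- rowsum(xn, assign)
  counts <- tabulate(assign, k)
  # online refinement: single-point moves with self-excluded own-centroid
  for (pass in seq_len(online_passes)) {
    moved <- FALSE
    cn <- sqrt(rowSums(sums^2))
    cen <- sums / ifelse(cn > 0, cn, 1)
    for (i in seq_len(n)) {
      a <- assign[i]
      if (counts[a] <= 1L) next
      sim <- as.vector(cen %*% xn[i, ])
      own <- sums[a, ] - xn[i, ]
      on2 <- sqrt(sum(own^2))
      sim[a] <- if (on2 > 0) sum(own * xn[i, ]) / on2 else -Inf
      b <- which.max(sim)
      if (b != a && sim[b] > sim[a] + 1e-12) {
        sums[a, ] <- own; sums[b, ] <- sums[b, ] + xn[i, ]
        counts[a] <- counts[a] - 1L; counts[b] <- counts[b] + 1L
        assign[i] <- b
        cen[a, ] <- if (on2 > 0) own / on2 else own
        bn <- sqrt(sum(sums[b, ]^2))
        cen[b, ] <- if (bn > 0) sums[b, ] / bn else sums[b, ]
        moved <- TRUE
      }
    }
    if (!moved) break
  }
  cn <- sqrt(rowSums(sums^2))
  cen <- sums / ifelse(cn > 0, cn, 1)
  obj <- sum(1 - rowSums(xn * cen[assign, , drop = FALSE]))
  list(cluster = assign, objective = obj,
       centroid_means = sums / pmax(counts, 1))
}

#' ROI label map
#'
#' @param labels 2D integer matrix (0 = background, 1..K = ROI ids).
#' @param pixel_size Pixel size in um/pixel.
#' @return An object of class `roi_label_map`.
#' @export
roi_label_map <- function(labels, pixel_size = 2.9) {
  structure(list(labels = labels, pixel_size = pixel_size),
            class = "roi_label_map")
}

#' @export
print.roi_label_map <- function(x, ...) {
  cat(sprintf("<roi_label_map> %d x %d px, %d ROIs\n",
              nrow(x$labels), ncol(x$labels), max(x$labels)))
  invisible(x)
}

# Renumber labels 1..K by raster order of ROI centroids (row-major).
renumber_by_centroid <- function(labels) {
  ids <- sort(unique(labels[labels > 0]))
  if (!length(ids)) return(labels)
  cy <- vapply(ids, function(i) mean(row(labels)[labels == i]), 0)
  cx <- vapply(ids, function(i) mean(col(labels)[labels == i]), 0)
  o <- order(cy, cx)
  out <- labels
  out[labels > 0] <- match(labels[labels > 0], ids[o])
  out
}

#' Split spatially disconnected clusters into separate ROIs
#'
#' k-means ignores pixel positions, so one dynamical cluster can cover
#' several disjoint patches of the colony. Every 8-connected component of
#' every cluster becomes its own ROI; labels are renumbered 1..K by the
#' raster order of ROI centroids.
#'
#' @param assignment Integer cluster id per foreground pixel (as returned by
#'   [cluster_pixels()]), aligned with the foreground pixels of `mask`
#'   (column-major order) or with `pm$coords`.
#' @param mask A `colony_mask` or logical matrix.
#' @return A [roi_label_map()].
#' @export
split_disconnected <- function(assignment, mask) {
  m <- if (inherits(mask, "colony_mask")) mask$mask else mask
  idx <- which(m)
  if (length(idx) != length(assignment))
    stop("assignment length does not match mask foreground count", call. = FALSE)
  amap <- matrix(0L, nrow(m), ncol(m))
  amap[idx] <- as.integer(assignment)
  out <- matrix(0L, nrow(m), ncol(m))
  nxt <- 0L
  for (cl in sort(unique(assignment))) {
    comp <- cpp_label_components(matrix(as.integer(amap == cl), nrow(m)), 8L)
    ncomp <- max(comp)
    if (ncomp > 0) {
      out[comp > 0] <- comp[comp > 0] + nxt
      nxt <- nxt + ncomp
    }
  }
  roi_label_map(renumber_by_centroid(out))
}

#' Prune ROIs below a minimum area
#'
#' ROIs smaller than `min_area_px2` (default 12 px, ~101 um^2 at 2.9 um/px)
#' reflect noise pixels and are returned to background; surviving labels are
#' renumbered contiguously by centroid raster order.
#'
#' @param label_map A [roi_label_map()].
#' @param min_area_px2 Minimum ROI area in pixels (default 12).
#' @return A [roi_label_map()].
#' @export
prune_small <- function(label_map, min_area_px2 = 12) {
  check_count(min_area_px2, "min_area_px2", min = 1L)
  lab <- label_map$labels
  n <- max(lab)
  if (n == 0) stop("label map has no ROIs", call. = FALSE)
  area <- tabulate(lab[lab > 0], nbins = n)
  drop <- which(area < min_area_px2)
  lab[lab %in% drop] <- 0L
  if (max(lab) == 0 || all(lab == 0))
    stop(paste("all ROIs fall below the minimum area; review the mask,",
               "clustering and `min_area_px2` parameters"), call. = FALSE)
  roi_label_map(renumber_by_centroid(lab), label_map$pixel_size)
}

#' Extract per-ROI fluorescence traces
#'
#' Integrates (averages) background-subtracted fluorescence over each ROI's
#' pixels per frame, estimates the baseline F0 as a robust minimum of the
#' trace (the `baseline_percentile` quantile; 0 gives the strict minimum),
#' and forms the normalized trace `dF/F0 = (F - F0)/F0`.
#'
#' @param corrected A `corrected_stack`, [timelapse_stack()] or 3D array of
#'   background-subtracted fluorescence.
#' @param label_map A [roi_label_map()] sharing the stack's frame size.
#' @param frame_interval Seconds per frame (default 1; taken from the stack
#'   when it is a `timelapse_stack`).
#' @param baseline_percentile Percentile (0-100) used as the robust minimum
#'   for F0 (default 1).
#' @return A `roi_trace_set`: list with `time` (s), `f` (t x K raw trace
#'   matrix), `norm` (t x K dF/F0 matrix), `f0`, `area_px2`, `centroid`
#'   (K x 2), and `roi_id`.
#' @export
extract_traces <- function(corrected, label_map, frame_interval = NULL,
                           baseline_percentile = 1) {
  arr <- if (inherits(corrected, "corrected_stack")) corrected$data else arr_3d(corrected)
  if (is.null(frame_interval))
    frame_interval <- if (inherits(corrected, "timelapse_stack"))
      corrected$frame_interval else 1
  lab <- label_map$labels
  d <- dim(arr)
  if (!all(dim(lab) == d[1:2]))
    stop("label map and stack differ in frame size", call. = FALSE)
  K <- max(lab)
  if (K == 0) stop("label map has no ROIs", call. = FALSE)
  idx <- which(lab > 0)
  grp <- lab[idx]
  flat <- matrix(arr, d[1] * d[2], d[3])[idx, , drop = FALSE]
  sums <- rowsum(flat, grp)
  area <- tabulate(grp, nbins = K)
  if (any(area == 0))
    stop(sprintf("labels absent from map: %s",
                 paste(which(area == 0), collapse = ", ")), call. = FALSE)
  f <- t(sums / area)                             # t x K mean trace
  f0 <- apply(f, 2, quantile, probs = baseline_percentile / 100, names = FALSE)
  f0 <- pmax(f0, 1e-9)
  norm <- sweep(sweep(f, 2, f0), 2, f0, "/")
  cy <- vapply(seq_len(K), function(i) mean(row(lab)[lab == i]), 0)
  cx <- vapply(seq_len(K), function(i) mean(col(lab)[lab == i]), 0)
  structure(list(time = (seq_len(d[3]) - 1) * frame_interval,
                 f = f, norm = norm, f0 = f0, area_px2 = area,
                 centroid = cbind(row = cy, col = cx),
                 roi_id = seq_len(K),
                 frame_interval = frame_interval),
            class = "roi_trace_set")
}

#' @export
print.roi_trace_set <- function(x, ...) {
  cat(sprintf("<roi_trace_set> %d ROIs x %d time points (%g s interval)\n",
              length(x$roi_id), length(x$time), x$frame_interval))
  invisible(x)
}

#' Exclude non-responsive ROIs
#'
#' Drops ROIs whose maximum fluorescence increase within a window after the
#' first stimulus onset is below `threshold` times baseline (default: dF/F0
#' < 1.0, i.e. less than 100% of baseline, within 5 min). Typical evoked
#' responses reach ~250% dF/F0, so excluded ROIs are dim non-viable regions
#' or constitutively bright ones without detectable waves.
#'
#' @param traces A `roi_trace_set`.
#' @param protocol A [stimulus_protocol()] with at least one pulse.
#' @param threshold Minimum peak dF/F0 in the window (default 1.0).
#' @param window_s Window length after first onset, seconds (default 300).
#' @return The filtered `roi_trace_set`, with an `exclusions` attribute: a
#'   data frame of dropped ROI ids, their peak response and the reason.
#' @export
exclude_nonresponsive <- function(traces, protocol, threshold = 1.0,
                                  window_s = 300) {
  if (nrow(protocol) < 1)
    stop("protocol must contain at least one pulse", call. = FALSE)
  on <- protocol$on_s[1]
  sel <- traces$time >= on & traces$time <= on + window_s
  peak <- apply(traces$norm[sel, , drop = FALSE], 2, max)
  keep <- peak >= threshold
  excl <- data.frame(roi_id = traces$roi_id[!keep],
                     peak_dff0 = peak[!keep],
                     reason = sprintf("max dF/F0 %.3g < %.3g within %gs of stimulus",
                                      peak[!keep], threshold, window_s))
  out <- traces
  out$f <- traces$f[, keep, drop = FALSE]
  out$norm <- traces$norm[, keep, drop = FALSE]
  out$f0 <- traces$f0[keep]
  out$area_px2 <- traces$area_px2[keep]
  out$centroid <- traces$centroid[keep, , drop = FALSE]
  out$roi_id <- traces$roi_id[keep]
  attr(out, "exclusions") <- excl
  out
}
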