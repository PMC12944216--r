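#' Build a synthetic protonemal colony geometry
#'
#' Generates a branching filamentous colony: filaments radiate from a common
#' center as gently wiggling polylines, each partitioned into contiguous
#' cells. The outermost cell of every filament is a tip cell, typed
#' caulonemal (CA, thinner) or chloronemal (CH, wider) per filament; interior
#' cells are the matching subapical type (CAs/CHs); cells that spawn a side
#' branch are typed B. Every CA tip cell carries an apical sub-region (CA*)
#' covering its outermost stretch, the fast-oscillating tip domain. Cells are
#' further divided lengthwise into regions of roughly `region_length_um`,
#' which are the ground-truth ROIs (real cells are typically resolved as 1-3
#' ROIs each).
#'
#' @param seed Integer seed; output is deterministic for a fixed seed.
#' @param n_filaments Number of primary filaments (>= 1).
#' @param cells_per_filament Cells per primary filament (>= 1).
#' @param branch_prob Probability that an interior cell spawns a branch.
#' @param cell_length_um,cell_length_sd Cell length distribution (um).
#' @param width_ca_um,width_ch_um Filament widths by lineage (um).
#' @param region_length_um Target ROI length along the filament (um).
#' @param tip_region_um Length of the CA* apical sub-region (um).
#' @param branch_cells Number of cells on each side branch.
#' @return A `colony_geometry`: list with `filaments` (list of polyline
#'   matrices, um), `cells` (data frame: cell_id, filament_id, s0_um, s1_um,
#'   width_um, cell_type), and `regions` (data frame: region_id, cell_id,
#'   filament_id, s0_um, s1_um, region_type).
#' @export
build_geometry <- function(seed, n_filaments, cells_per_filament,
                           branch_prob = 0.15,
                           cell_length_um = 95, cell_length_sd = 12,
                           width_ca_um = 14, width_ch_um = 19,
                           region_length_um = 65, tip_region_um = 25,
                           branch_cells = 2) {
  check_count(n_filaments, "n_filaments", min = 1L)
  check_count(cells_per_filament, "cells_per_filament", min = 1L)
  with_seed(seed, {
    filaments <- list()
    cells <- list()
    pending <- list()  # branch requests: origin point, heading, lineage
    for (i in seq_len(n_filaments)) {
      ang <- 2 * pi * (i - 1) / n_filaments + runif(1, -0.25, 0.25)
      origin <- 8 * c(cos(ang), sin(ang))
      lineage <- if (runif(1) < 0.5) "CA" else "CH"
      pending[[length(pending) + 1L]] <-
        list(origin = origin, heading = ang, lineage = lineage,
             n_cells = cells_per_filament, can_branch = TRUE)
    }
    fid <- 0L
    while (length(pending)) {
      req <- pending[[1]]; pending <- pending[-1]
      fid <- fid + 1L
      len_cells <- pmax(40, rnorm(req$n_cells, cell_length_um, cell_length_sd))
      L <- sum(len_cells)
      # polyline with heading jitter, 20 um steps
      nstep <- ceiling(L / 20)
      headings <- req$heading + cumsum(c(0, rnorm(nstep, 0, 0.1)))
      step_len <- c(rep(20, nstep - 1), L - 20 * (nstep - 1))
      pts <- matrix(0, nstep + 1, 2)
      pts[1, ] <- req$origin
      for (s in seq_len(nstep))
        pts[s + 1, ] <- pts[s, ] + step_len[s] * c(cos(headings[s]), sin(headings[s]))
      filaments[[fid]] <- pts
      width <- if (req$lineage == "CA") width_ca_um else width_ch_um
      s1 <- cumsum(len_cells)
      s0 <- c(0, head(s1, -1))
      type <- rep(paste0(req$lineage, "s"), req$n_cells)
      type[req$n_cells] <- req$lineage                 # outermost cell is the tip
      # branches sprout from interior cells
      if (req$can_branch && req$n_cells > 2) {
        for (ci in 2:(req$n_cells - 1)) {
          if (runif(1) < branch_prob) {
            type[ci] <- "B"
            smid <- (s0[ci] + s1[ci]) / 2
            bp <- point_at_arclength(pts, smid)
            side <- sample(c(-1, 1), 1)
            blin <- if (runif(1) < 0.8) "CH" else "CA"
            pending[[length(pending) + 1L]] <-
              list(origin = bp$point,
                   heading = bp$heading + side * (pi / 3 + runif(1, -0.2, 0.2)),
                   lineage = blin, n_cells = branch_cells, can_branch = FALSE)
          }
        }
      }
      cells[[fid]] <- data.frame(filament_id = fid, s0_um = s0, s1_um = s1,
                                 width_um = width, cell_type = type,
                                 stringsAsFactors = FALSE)
    }
    cells <- do.call(rbind, cells)
    cells$cell_id <- seq_len(nrow(cells))
    regions <- make_regions(cells, region_length_um, tip_region_um)
    structure(list(filaments = filaments, cells = cells, regions = regions),
              class = "colony_geometry")
  })
}

# split each cell lengthwise into ROI regions; CA tip cells get an apical CA*
make_regions <- function(cells, region_length_um, tip_region_um) {
  out <- list()
  for (i in seq_len(nrow(cells))) {
    ce <- cells[i, ]
    len <- ce$s1_um - ce$s0_um
    segs <- list()
    if (ce$cell_type == "CA" && len > tip_region_um * 1.5) {
      body <- len - tip_region_um
      nb <- max(1L, round(body / region_length_um))
      br <- ce$s0_um + body * (0:nb) / nb
      for (j in seq_len(nb))
        segs[[j]] <- c(br[j], br[j + 1], "CA")
      segs[[nb + 1]] <- c(ce$s1_um - tip_region_um, ce$s1_um, "CA*")
    } else {
      nr <- max(1L, round(len / region_length_um))
      br <- ce$s0_um + len * (0:nr) / nr
      for (j in seq_len(nr))
        segs[[j]] <- c(br[j], br[j + 1], ce$cell_type)
    }
    out[[i]] <- data.frame(cell_id = ce$cell_id, filament_id = ce$filament_id,
                           s0_um = as.numeric(vapply(segs, `[`, "", 1)),
                           s1_um = as.numeric(vapply(segs, `[`, "", 2)),
                           region_type = vapply(segs, `[`, "", 3),
                           stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, out)
  out$region_id <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

# point and local heading at arclength s along a polyline
point_at_arclength <- function(pts, s) {
  seg <- diff(pts)
  lens <- sqrt(rowSums(seg^2))
  cum <- c(0, cumsum(lens))
  j <- max(1L, findInterval(s, cum, rightmost.closed = TRUE))
  j <- min(j, nrow(seg))
  f <- (s - cum[j]) / lens[j]
  list(point = pts[j, ] + f * seg[j, ],
       heading = atan2(seg[j, 2], seg[j, 1]))
}

#' @export
print.colony_geometry <- function(x, ...) {
  cat(sprintf("<colony_geometry> %d filaments, %d cells, %d regions (%s)\n",
              length(x$filaments), nrow(x$cells), nrow(x$regions),
              paste(sprintf("%s:%d", names(table(x$cells$cell_type)),
                            as.integer(table(x$cells$cell_type))),
                    collapse = " ")))
  invisible(x)
}
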