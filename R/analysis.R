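# Aggregation-center detection and quantification.
#
# "Aggregation center" is operationalized as a density-connected cluster of
# cell centroids under the min-image metric: members have at least k other
# cells within the detection radius and are linked through neighbors at
# that radius. The largest cluster's rasterized footprint is classified
# into ROUND / HOLED / LONG_MULTI shape classes, and ROUND_STABLE requires
# the class to persist over subsequent snapshots.

#' Detect aggregation centers by density-connected clustering
#'
#' A cluster is a maximal set of cells in which every member has at least
#' `k` neighbors within `radius` (min-image metric) and members are linked
#' through chains of such neighbors. Clusters smaller than `min_cells` are
#' discarded.
#'
#' @param positions n x 2 matrix of cell centroids (um, wrapped).
#' @param domain domain specification (a `myxo_config` works).
#' @param radius neighbor radius (um); default two nominal cell lengths.
#' @param k minimum neighbor count for cluster membership; `NULL` (the
#'   default) calibrates against the scene's mean density,
#'   `max(10, 2 x expected uniform neighbor count)`, so that a uniform
#'   random scatter yields no clusters at any density. In sparse scenes
#'   this reduces to 10.
#' @param min_cells minimum cluster size; default 2 percent of the
#'   population (at least 2).
#' @return A list with `labels` (0 = unclustered), `clusters` (list of
#'   member index vectors, largest first), `sizes`, `k`, and
#'   `recruitment_fraction` (fraction of all cells in any qualifying
#'   cluster).
#' @export
detect_aggregates <- function(positions, domain, radius = 8, k = NULL,
                              min_cells = NULL) {
  d <- as_domain(domain)
  n <- nrow(positions)
  if (is.null(k)) {
    bg <- n * pi * radius^2 / (d$width * d$height)
    k <- max(10, ceiling(2 * bg))
  }
  if (is.null(min_cells)) min_cells <- max(2L, ceiling(0.02 * n))
  labels <- density_cluster_cpp(positions, d$width, d$height, radius,
                                as.integer(k))
  sizes <- tabulate(labels)
  keep <- which(sizes >= min_cells)
  labels[!(labels %in% keep)] <- 0L
  ord <- keep[order(sizes[keep], decreasing = TRUE)]
  clusters <- lapply(ord, function(l) which(labels == l))
  # relabel 1..m by decreasing size
  new_labels <- integer(n)
  for (j in seq_along(clusters)) new_labels[clusters[[j]]] <- j
  list(labels = new_labels, clusters = clusters,
       sizes = vapply(clusters, length, integer(1)), k = k,
       recruitment_fraction = if (n > 0) sum(new_labels > 0) / n else 0)
}

#' Rasterize a cluster footprint
#'
#' Unwraps the member positions around a reference member (min-image) and
#' stamps a disc of radius `stamp` around each on a square lattice. Returns
#' `NULL` when the cluster cannot be unwrapped consistently (it spans the
#' torus), in which case no compact shape exists.
#'
#' @param positions member centroid positions (wrapped).
#' @param domain domain specification.
#' @param bin_size raster bin size (um).
#' @param stamp stamp radius (um), about half a cell length.
#' @param close_radius morphological closing radius (um): dilate then erode
#'   by this much to smooth the point-sampling raggedness of the boundary
#'   before shape metrics are taken. Must stay below half the smallest hole
#'   size of interest.
#' @return `list(mask, counts, bin_size)` or `NULL`; `mask` is a logical
#'   occupancy matrix, `counts` the per-bin member counts.
#' @export
rasterize_cluster <- function(positions, domain, bin_size = 1, stamp = 2,
                              close_radius = 3) {
  d <- as_domain(domain)
  n <- nrow(positions)
  if (n == 0) return(NULL)
  ref <- positions[1, , drop = FALSE]
  disp <- min_image_cpp(ref[rep(1, n), , drop = FALSE], positions,
                        d$width, d$height)
  ext <- apply(disp, 2, function(z) diff(range(z)))
  if (any(ext > 0.45 * c(d$width, d$height))) return(NULL)
  xy <- sweep(disp, 2, apply(disp, 2, min), "-")
  pad <- ceiling((stamp + close_radius) / bin_size) + 2L
  nxb <- ceiling(max(xy[, 1]) / bin_size) + 2L * pad + 1L
  nyb <- ceiling(max(xy[, 2]) / bin_size) + 2L * pad + 1L
  ix <- pmin(nxb, pmax(1L, as.integer(xy[, 1] %/% bin_size) + pad + 1L))
  iy <- pmin(nyb, pmax(1L, as.integer(xy[, 2] %/% bin_size) + pad + 1L))
  counts <- matrix(0L, nxb, nyb)
  for (i in seq_len(n)) counts[ix[i], iy[i]] <- counts[ix[i], iy[i]] + 1L
  mask <- dilate_disc(counts > 0L, stamp / bin_size)
  if (close_radius > 0) {
    rb <- close_radius / bin_size
    # closing fills point-sampling gaps, opening shaves ragged spikes
    mask <- !dilate_disc(!dilate_disc(mask, rb), rb)
    mask <- dilate_disc(!dilate_disc(!mask, rb), rb)
  }
  list(mask = mask, counts = counts, bin_size = bin_size)
}

# internal: dilate a logical matrix by a disc of radius r (in bins)
dilate_disc <- function(mask, r) {
  ri <- as.integer(ceiling(r))
  offs <- expand.grid(dx = -ri:ri, dy = -ri:ri)
  offs <- offs[offs$dx^2 + offs$dy^2 <= r^2, ]
  out <- matrix(FALSE, nrow(mask), ncol(mask))
  occupied <- which(mask, arr.ind = TRUE)
  if (nrow(occupied) == 0) return(out)
  for (j in seq_len(nrow(offs))) {
    sx <- occupied[, 1] + offs$dx[j]
    sy <- occupied[, 2] + offs$dy[j]
    ok <- sx >= 1 & sx <= nrow(mask) & sy >= 1 & sy <= ncol(mask)
    out[cbind(sx[ok], sy[ok])] <- TRUE
  }
  out
}

# internal: flood fill of TRUE bins reachable from the matrix border
flood_from_border <- function(open) {
  reach <- matrix(FALSE, nrow(open), ncol(open))
  reach[1, ] <- open[1, ]
  reach[nrow(open), ] <- open[nrow(open), ]
  reach[, 1] <- open[, 1]
  reach[, ncol(open)] <- open[, ncol(open)]
  repeat {
    grown <- reach
    grown[-1, ] <- grown[-1, ] | reach[-nrow(reach), ]
    grown[-nrow(reach), ] <- grown[-nrow(reach), ] | reach[-1, ]
    grown[, -1] <- grown[, -1] | reach[, -ncol(reach)]
    grown[, -ncol(reach)] <- grown[, -ncol(reach)] | reach[, -1]
    grown <- grown & open
    if (identical(grown, reach)) return(reach)
    reach <- grown
  }
}

# internal: count 4-connected components of a logical matrix
count_components <- function(mask) {
  left <- mask
  n <- 0L
  while (any(left)) {
    n <- n + 1L
    seed <- which(left, arr.ind = TRUE)[1, , drop = FALSE]
    comp <- matrix(FALSE, nrow(left), ncol(left))
    comp[seed] <- TRUE
    repeat {
      grown <- comp
      grown[-1, ] <- grown[-1, ] | comp[-nrow(comp), ]
      grown[-nrow(comp), ] <- grown[-nrow(comp), ] | comp[-1, ]
      grown[, -1] <- grown[, -1] | comp[, -ncol(comp)]
      grown[, -ncol(comp)] <- grown[, -ncol(comp)] | comp[, -1]
      grown <- grown & left
      if (identical(grown, comp)) break
      comp <- grown
    }
    left <- left & !comp
  }
  n
}

#' Classify a cluster footprint shape
#'
#' Computes circularity `c = 4*pi*A / P^2` on the filled footprint (the
#' staircase perimeter is corrected by the factor pi/4, which is exact for
#' smooth convex shapes averaged over orientations), an interior-hole flag
#' (enclosed empty area > 5 percent of the footprint), the principal-axis
#' elongation ratio, and the number of member-density peaks (4-connected
#' components above half the peak smoothed density).
#'
#' Classes, in priority order: fewer than 3 occupied bins gives `NONE`;
#' an interior hole gives `HOLED`; elongation >= 3 or >= 3 density peaks
#' gives `LONG_MULTI`; circularity >= 0.6 gives `ROUND`; otherwise `NONE`.
#'
#' @param raster a raster from [rasterize_cluster()] (or `NULL`).
#' @return A list with `class` and the metrics (`area`, `circularity`,
#'   `hole_fraction`, `axis_ratio`, `n_peaks`).
#' @export
shape_classify <- function(raster) {
  degenerate <- list(class = "NONE", area = 0, circularity = NA_real_,
                     hole_fraction = NA_real_, axis_ratio = NA_real_,
                     n_peaks = 0L)
  if (is.null(raster) || sum(raster$mask) < 3) return(degenerate)
  mask <- raster$mask
  h <- raster$bin_size
  area <- sum(mask) * h^2

  # staircase perimeter: count exposed 4-neighbor edges
  padm <- rbind(FALSE, cbind(FALSE, mask, FALSE), FALSE)
  nr <- nrow(padm)
  nc <- ncol(padm)
  edges <- sum(padm[-1, ] != padm[-nr, ]) + sum(padm[, -1] != padm[, -nc])
  perim <- edges * h * pi / 4
  circ <- min(1, 4 * pi * area / perim^2)

  # interior holes: empty bins not reachable from the border
  reach <- flood_from_border(!mask)
  hole_bins <- sum(!mask & !reach)
  hole_fraction <- hole_bins / sum(mask)

  # principal-axis elongation of the footprint
  idx <- which(mask, arr.ind = TRUE)
  cen <- colMeans(idx)
  cc <- sweep(idx, 2, cen)
  cov <- crossprod(cc) / nrow(cc) + diag(1e-9, 2)
  ev <- eigen(cov, symmetric = TRUE, only.values = TRUE)$values
  axis_ratio <- sqrt(max(ev) / max(min(ev), 1e-12))

  # density peaks from the member counts (box-smoothed)
  n_peaks <- 1L
  if (!is.null(raster$counts)) {
    sm <- box_smooth(raster$counts, 2L)
    thr <- 0.5 * max(sm)
    if (thr > 0) n_peaks <- count_components(sm >= thr)
  }

  cls <- if (hole_fraction > 0.05) {
    "HOLED"
  } else if (axis_ratio >= 3 || n_peaks >= 3) {
    "LONG_MULTI"
  } else if (circ >= 0.6) {
    "ROUND"
  } else {
    "NONE"
  }
  list(class = cls, area = area, circularity = circ,
       hole_fraction = hole_fraction, axis_ratio = axis_ratio,
       n_peaks = n_peaks)
}

# internal: (2r+1)-square box blur with zero padding
box_smooth <- function(m, r) {
  out <- matrix(0, nrow(m), ncol(m))
  for (dx in -r:r) {
    for (dy in -r:r) {
      src <- m
      if (dx > 0) src <- rbind(matrix(0, dx, ncol(m)), src[seq_len(nrow(m) - dx), , drop = FALSE])
      if (dx < 0) src <- rbind(src[-seq_len(-dx), , drop = FALSE], matrix(0, -dx, ncol(m)))
      if (dy > 0) src <- cbind(matrix(0, nrow(m), dy), src[, seq_len(ncol(m) - dy), drop = FALSE])
      if (dy < 0) src <- cbind(src[, -seq_len(-dy), drop = FALSE], matrix(0, nrow(m), -dy))
      out <- out + src
    }
  }
  out
}

#' Aggregate report for a scene or simulation
#'
#' Runs [detect_aggregates()] on cell centroids and classifies every
#' qualifying cluster's shape.
#'
#' @param x a `myxo_sim` (final snapshot used) or an n x 2 centroid matrix.
#' @param domain required when `x` is a matrix.
#' @param ... passed to [detect_aggregates()].
#' @return An `aggregate_report`: a list with the `clusters` data frame
#'   (size, centroid, area, circularity, shape class),
#'   `recruitment_fraction`, `largest_class`, and the raw `detection`.
#' @export
aggregate_report <- function(x, domain = NULL, ...) {
  if (inherits(x, "myxo_sim")) {
    pos <- x$snapshots[[length(x$snapshots)]][, 1:2, drop = FALSE]
    domain <- x$config
  } else {
    pos <- x[, 1:2, drop = FALSE]
    if (is.null(domain)) stop("domain required for a position matrix")
  }
  d <- as_domain(domain)
  det <- detect_aggregates(pos, d, ...)
  m <- length(det$clusters)
  rows <- vector("list", m)
  for (j in seq_len(m)) {
    mem <- pos[det$clusters[[j]], , drop = FALSE]
    ras <- rasterize_cluster(mem, d)
    sh <- shape_classify(ras)
    disp <- min_image_cpp(mem[rep(1, nrow(mem)), , drop = FALSE], mem,
                          d$width, d$height)
    cen <- (mem[1, ] + colMeans(disp)) %% c(d$width, d$height)
    rows[[j]] <- data.frame(
      cluster = j, n_cells = nrow(mem), x = cen[1], y = cen[2],
      area = sh$area, circularity = sh$circularity,
      shape_class = sh$class, stringsAsFactors = FALSE
    )
  }
  clusters <- if (m > 0) do.call(rbind, rows) else
    data.frame(cluster = integer(0), n_cells = integer(0), x = numeric(0),
               y = numeric(0), area = numeric(0), circularity = numeric(0),
               shape_class = character(0), stringsAsFactors = FALSE)
  out <- list(clusters = clusters,
              recruitment_fraction = det$recruitment_fraction,
              largest_class = if (m > 0) clusters$shape_class[1] else "NONE",
              detection = det)
  class(out) <- "aggregate_report"
  out
}

#' @export
print.aggregate_report <- function(x, ...) {
  cat(sprintf(
    "<aggregate_report> %d cluster(s), recruitment %.2f, largest: %s\n",
    nrow(x$clusters), x$recruitment_fraction, x$largest_class))
  if (nrow(x$clusters) > 0) print(x$clusters, row.names = FALSE)
  invisible(x)
}

#' Time to complete initial aggregation
#'
#' Scans a snapshot series for the earliest time at which the recruitment
#' fraction reaches `recruitment_threshold` and the largest cluster is
#' round, requiring the round class to persist over the following
#' `persist_min` minutes of snapshots (a round-and-stable aggregate).
#'
#' @param snapshots list of n x >=2 matrices (centroids first two columns)
#'   or a `myxo_sim`.
#' @param times snapshot times in minutes (taken from the simulation when
#'   `snapshots` is a `myxo_sim`).
#' @param domain domain specification (from the simulation if omitted).
#' @param recruitment_threshold minimum recruitment fraction.
#' @param persist_min persistence window (min).
#' @param ... passed to [detect_aggregates()].
#' @return A list with `time_min` (`NA` when not reached), `reached`, and a
#'   per-snapshot data frame `series` (time, recruitment, largest class).
#' @export
time_to_aggregation <- function(snapshots, times = NULL, domain = NULL,
                                recruitment_threshold = 0.8,
                                persist_min = 60, ...) {
  if (inherits(snapshots, "myxo_sim")) {
    times <- snapshots$snapshot_times
    domain <- snapshots$config
    snapshots <- snapshots$snapshots
  }
  d <- as_domain(domain)
  ns <- length(snapshots)
  rec <- numeric(ns)
  cls <- character(ns)
  for (s in seq_len(ns)) {
    pos <- snapshots[[s]][, 1:2, drop = FALSE]
    det <- detect_aggregates(pos, d, ...)
    rec[s] <- det$recruitment_fraction
    if (length(det$clusters) > 0) {
      ras <- rasterize_cluster(pos[det$clusters[[1]], , drop = FALSE], d)
      cls[s] <- shape_classify(ras)$class
    } else {
      cls[s] <- "NONE"
    }
  }
  series <- data.frame(time_min = times, recruitment = rec,
                       largest_class = cls, stringsAsFactors = FALSE)
  t_star <- NA_real_
  for (s in seq_len(ns)) {
    if (rec[s] >= recruitment_threshold && cls[s] == "ROUND") {
      horizon <- which(times > times[s] & times <= times[s] + persist_min)
      if (all(cls[horizon] == "ROUND")) {
        t_star <- times[s]
        break
      }
    }
  }
  list(time_min = t_star, reached = !is.na(t_star), series = series)
}

#' Behavioral statistics from an event log
#'
#' Recovers the population statistics of reversal and active turning from a
#' simulation event log, mirroring the single-cell motility measurement
#' protocol. Event times are quantized to the step grid, so every interval
#' carries a positive bias of about `dt / 2`; the `*_corrected` means
#' subtract it.
#'
#' @param events the `events` data frame of a `myxo_sim` (log level >= 1).
#' @param dt simulation time step (min).
#' @return A list of summaries: `reversal` (pooled inter-reversal
#'   intervals; clock reversals and pole-to-pole collision reversals both
#'   reset the clock), `turning` (angle magnitudes, signed left fraction,
#'   intervals), and `modes` (logged mode counts). Each interval summary
#'   also carries `cell_means`, the per-cell mean intervals: intervals are
#'   clustered within cells (a cell's reversal period is a single draw), so
#'   population standard errors should be computed across cells. Cells with fewer than
#'   two events contribute no intervals; with no intervals at all the means
#'   are reported as `NA` with `n = 0`, not as zero.
#' @export
behavior_stats <- function(events, dt = 1 / 3) {
  stopifnot(is.data.frame(events))
  rev_ev <- events[events$mode == "REVERSED" |
                     (events$mode == "COLLISION_POLE" &
                        events$moved == 0), , drop = FALSE]
  rev_int <- pooled_intervals(rev_ev)
  turn_ev <- events[events$mode == "ACTIVE_TURN", , drop = FALSE]
  turn_int <- pooled_intervals(turn_ev)
  rev_cell <- per_cell_means(rev_ev)
  turn_cell <- per_cell_means(turn_ev)
  ang <- abs(turn_ev$angle_deg)
  list(
    reversal = c(interval_summary(rev_int, dt),
                 list(cell_means = rev_cell)),
    turning = c(
      list(
        angle_mean = if (length(ang)) mean(ang) else NA_real_,
        angle_sd = if (length(ang) > 1) stats::sd(ang) else NA_real_,
        angle_se = if (length(ang) > 1) {
          stats::sd(ang) / sqrt(length(ang))
        } else {
          NA_real_
        },
        n_turns = length(ang),
        left_fraction = if (length(ang)) {
          mean(turn_ev$angle_deg > 0)
        } else {
          NA_real_
        }
      ),
      interval_summary(turn_int, dt),
      list(cell_means = turn_cell)
    ),
    modes = table(events$mode)
  )
}

# per-cell mean inter-event interval (cells with >= 2 events)
per_cell_means <- function(ev) {
  if (nrow(ev) < 2) return(numeric(0))
  out <- vapply(split(ev$time_min, ev$cell), function(t) {
    if (length(t) < 2) NA_real_ else mean(diff(sort(t)))
  }, numeric(1))
  out[!is.na(out)]
}

# pooled within-cell consecutive event intervals
pooled_intervals <- function(ev) {
  if (nrow(ev) < 2) return(numeric(0))
  unlist(lapply(split(ev$time_min, ev$cell), function(t) {
    if (length(t) < 2) numeric(0) else diff(sort(t))
  }), use.names = FALSE)
}

interval_summary <- function(x, dt) {
  n <- length(x)
  list(interval_mean = if (n) mean(x) else NA_real_,
       interval_mean_corrected = if (n) mean(x) - dt / 2 else NA_real_,
       interval_sd = if (n > 1) stats::sd(x) else NA_real_,
       interval_se = if (n > 1) stats::sd(x) / sqrt(n) else NA_real_,
       n_intervals = n)
}
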