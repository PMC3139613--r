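# Single-cell representation and the per-cell motility rules.
#
# A cell is a string of 3-5 nodes connected by segments of equal length L;
# node 1 is the leading pole. The body trails the leading pole along its
# recorded waypoint track at arc-length spacing L, which preserves the
# equal-segment invariant for any step length. These R-level operations
# mirror the rules applied by the compiled colony engine and share its
# C++ primitives for the nontrivial geometry.

# truncated-normal sampler (rejection; lower bound keeps periods positive)
rtnorm <- function(n, mean, sd, lower = 0.1, upper = Inf) {
  out <- rnorm(n, mean, sd)
  bad <- which(out <= lower | out > upper)
  while (length(bad) > 0) {
    out[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] <= lower | out[bad] > upper]
  }
  out
}

#' Sample per-cell behavioral parameters
#'
#' Lengths are uniform on the configured range; the node count is
#' `round(length)` clamped to 3-5 (so segments are about 1-2 um); width is
#' 0.1 of length; the baseline reversal period and the active-turning
#' interval are truncated-normal draws. Sampling uses R's RNG: call
#' `set.seed()` first for reproducibility.
#'
#' @param n number of cells.
#' @param config a [myxo_config()].
#' @return A data frame with columns `length`, `n_nodes`, `width`,
#'   `seg_len`, `period`, `turn_interval`.
#' @export
sample_cell_params <- function(n, config = myxo_config()) {
  len <- runif(n, config$length_range[1], config$length_range[2])
  n_nodes <- pmin(5L, pmax(3L, as.integer(round(len))))
  data.frame(
    length = len,
    n_nodes = n_nodes,
    width = config$width_ratio * len,
    seg_len = len / (n_nodes - 1L),
    period = rtnorm(n, config$reversal_mean, config$reversal_sd),
    turn_interval = rtnorm(n, config$turn_interval_mean,
                           config$turn_interval_sd)
  )
}

#' Construct a straight cell
#'
#' Builds a cell with its leading pole at `pole`, body extending backwards
#' along `-orientation`, and a waypoint track equal to the body.
#'
#' @param pole leading-pole position (2-vector, um).
#' @param angle heading angle in degrees (0 = +x).
#' @param length cell length (um).
#' @param config a [myxo_config()] supplying the remaining parameters.
#' @param id integer id.
#' @param phase initial reversal-clock phase (min).
#' @param period baseline reversal period (min); sampled if `NULL`.
#' @return A list of class `myxo_cell` with wrapped `nodes` (m x 2, leading
#'   pole first), the unwrapped waypoint `track` (oldest to newest), sampled
#'   parameters, and clock state.
#' @export
make_cell <- function(pole, angle = 0, length = 4, config = myxo_config(),
                      id = 1L, phase = 0, period = NULL) {
  n_nodes <- min(5L, max(3L, as.integer(round(length))))
  seg <- length / (n_nodes - 1L)
  dir <- c(cos(angle * pi / 180), sin(angle * pi / 180))
  nodes_u <- t(vapply(seq_len(n_nodes) - 1L,
                      function(k) pole - k * seg * dir, numeric(2)))
  cell <- list(
    id = as.integer(id),
    nodes = wrap_position(nodes_u, config),
    nodes_u = nodes_u,
    track = nodes_u[n_nodes:1, , drop = FALSE],  # oldest -> newest = pole
    n_nodes = n_nodes, length = length,
    width = config$width_ratio * length, seg_len = seg,
    speed = config$speed,
    period_base = if (is.null(period)) {
      rtnorm(1, config$reversal_mean, config$reversal_sd)
    } else {
      period
    },
    phase = phase, last_turn = 0,
    turn_interval = rtnorm(1, config$turn_interval_mean,
                           config$turn_interval_sd),
    domain = list(width = config$width, height = config$height,
                  dt = config$dt)
  )
  cell$period_cur <- cell$period_base
  class(cell) <- "myxo_cell"
  cell
}

#' Advance the reversal clock and fire a polarity reversal
#'
#' Adds `dt` to the clock phase; when the phase reaches the current period
#' the cell reverses: node order flips (the leading and lagging poles swap
#' functions), the orientation is thereby negated, the clock resets, the
#' waypoint track is replaced by the reversed body, and the cell does not
#' translate during that step.
#'
#' @param cell a `myxo_cell`.
#' @param dt time step (min).
#' @return `list(cell, reversed)` with the updated cell.
#' @export
check_reversal <- function(cell, dt) {
  cell$phase <- cell$phase + dt
  if (cell$phase < cell$period_cur - 1e-9) {
    return(list(cell = cell, reversed = FALSE))
  }
  m <- cell$n_nodes
  cell$track <- cell$nodes_u  # old chain, pole first = new oldest-first
  cell$nodes_u <- cell$nodes_u[m:1, , drop = FALSE]
  cell$nodes <- cell$nodes[m:1, , drop = FALSE]
  cell$phase <- 0
  list(cell = cell, reversed = TRUE)
}

#' Local cell density in the measuring domain
#'
#' Counts the other cells with at least one node inside the axis-aligned
#' square of side one cell length centered at the focal cell's node
#' centroid (minimum-image metric).
#'
#' @param cell a `myxo_cell`.
#' @param cells a list of `myxo_cell` (may include `cell` itself, matched
#'   by `id`).
#' @param domain domain specification; defaults to the cell's.
#' @return Integer neighbor count.
#' @export
local_density <- function(cell, cells, domain = NULL) {
  d <- as_domain(if (is.null(domain)) cell$domain else domain)
  others <- Filter(function(x) x$id != cell$id, cells)
  all <- c(list(cell), others)
  mat <- cells_to_matrix(all)
  dens <- local_density_all_cpp(mat$nodes, mat$n_nodes,
                                vapply(all, `[[`, numeric(1), "length"),
                                d$width, d$height)
  dens[1]
}

#' Modulate the reversal period by quorum sensing
#'
#' Called at a polarity reversal: if the local density falls in a class of
#' the quorum table, the current period is redrawn uniformly from that
#' class's range; otherwise it falls back to the baseline sampled period.
#'
#' @param cell a `myxo_cell`.
#' @param density local neighbor count.
#' @param table a quorum table, see [default_quorum_table()].
#' @return The updated cell.
#' @export
modulate_period <- function(cell, density, table = default_quorum_table()) {
  hit <- which(density >= table[, "dlo"] & density <= table[, "dhi"])
  if (length(hit) == 0) {
    cell$period_cur <- cell$period_base
  } else {
    r <- table[hit[1], ]
    cell$period_cur <- runif(1, r[["plo"]], min(r[["phi"]], 360))
  }
  cell
}

#' Detect a leading-pole collision
#'
#' The leading pole of the focal cell collides with a node of another cell
#' when their min-image distance is strictly less than one cell width (the
#' focal cell's). The nearest colliding node is returned; node index 1
#' distinguishes pole-to-pole from pole-to-side contact.
#'
#' @inheritParams local_density
#' @return `NULL`, or `list(partner, node, dist)` with the partner's id and
#'   1-based node index.
#' @export
detect_collision <- function(cell, cells, domain = NULL) {
  d <- as_domain(if (is.null(domain)) cell$domain else domain)
  others <- Filter(function(x) x$id != cell$id, cells)
  all <- c(list(cell), others)
  mat <- cells_to_matrix(all)
  hits <- detect_collision_cpp(mat$nodes, mat$n_nodes,
                               vapply(all, `[[`, numeric(1), "width"),
                               d$width, d$height)
  if (hits[1, "partner"] == 0) return(NULL)
  list(partner = all[[hits[1, "partner"]]]$id,
       node = as.integer(hits[1, "node"]),
       dist = unname(hits[1, "dist"]))
}

#' Acute-angle alignment in a pole-to-side collision
#'
#' Returns the partner's orientation with its sign chosen so that the angle
#' to the focal cell's own orientation is acute. A perpendicular tie
#' (zero dot product) is resolved by a random sign.
#'
#' @param cell,partner `myxo_cell` objects.
#' @return A unit 2-vector direction.
#' @export
resolve_pole_to_side <- function(cell, partner) {
  oi <- cell_orientation(cell)
  oj <- cell_orientation(partner)
  s <- sign(sum(oi * oj))
  if (s == 0) s <- sample(c(-1, 1), 1)
  s * oj
}

#' Pass-by-or-reverse in a pole-to-pole collision
#'
#' With probability 1/2 the cell slightly rotates its heading by an angle
#' drawn uniformly from `pass_range` (random sign) and moves on; otherwise
#' it performs a full polarity reversal (clock reset, no translation).
#'
#' @param cell a `myxo_cell`.
#' @param config a [myxo_config()] (supplies `pass_range`).
#' @return `list(cell, mode, direction)`; `direction` is `NULL` when the
#'   cell reversed.
#' @export
resolve_pole_to_pole <- function(cell, config = myxo_config()) {
  if (runif(1) < 0.5) {
    delta <- runif(1, config$pass_range[1], config$pass_range[2]) *
      sample(c(-1, 1), 1)
    dir <- rotate_vector(cell_orientation(cell), delta)
    list(cell = cell, mode = "COLLISION_POLE", direction = dir,
         angle = delta)
  } else {
    m <- cell$n_nodes
    cell$track <- cell$nodes_u
    cell$nodes_u <- cell$nodes_u[m:1, , drop = FALSE]
    cell$nodes <- cell$nodes[m:1, , drop = FALSE]
    cell$phase <- 0
    list(cell = cell, mode = "COLLISION_POLE", direction = NULL,
         angle = NA_real_)
  }
}

#' Spontaneous active turning
#'
#' When the time since the last active turn has reached the cell's turn
#' interval, the cell turns by an angle whose magnitude is
#' Normal(mean, sd) truncated to (0, max] with an equally probable left or
#' right sign; the interval is then redrawn.
#'
#' @param cell a `myxo_cell`.
#' @param now current time (min).
#' @param config a [myxo_config()] (turning parameters).
#' @return `list(cell, direction)`; `direction` is `NULL` when the timer
#'   has not elapsed.
#' @export
check_active_turn <- function(cell, now, config = myxo_config()) {
  if (now - cell$last_turn < cell$turn_interval - 1e-9) {
    return(list(cell = cell, direction = NULL, angle = NA_real_))
  }
  mag <- rtnorm(1, config$turn_mean, config$turn_sd, lower = 0,
                upper = config$turn_max)
  sgn <- sample(c(-1, 1), 1)
  dir <- rotate_vector(cell_orientation(cell), sgn * mag)
  cell$last_turn <- now
  cell$turn_interval <- rtnorm(1, config$turn_interval_mean,
                               config$turn_interval_sd)
  list(cell = cell, direction = dir, angle = sgn * mag)
}

#' One-hot per-step decision for a cell
#'
#' Applies the strict-priority motility algorithm: (a) reversal clock with
#' quorum modulation, (b) collision, (c) EPS trail following, (d) active
#' turning, else straight gliding along the tail-to-head orientation.
#' Exactly one mode results per step. Disabled subsystems are skipped
#' transparently.
#'
#' @param cell a `myxo_cell`.
#' @param cells list of all cells (neighbors read synchronously).
#' @param field a [slime_field()] or `NULL`.
#' @param now current time at the end of the step (min).
#' @param config a [myxo_config()].
#' @param exclude own fresh-trail bin indices for slime sensing.
#' @return `list(cell, mode, direction, angle)`; `direction` is `NULL` for
#'   a reversal (the cell does not translate that step).
#' @export
decide <- function(cell, cells, field, now, config = myxo_config(),
                   exclude = integer(0)) {
  # (a) reversal clock + quorum sensing
  if (config$reversal) {
    rv <- check_reversal(cell, config$dt)
    cell <- rv$cell
    if (rv$reversed) {
      if (config$quorum) {
        dens <- local_density(cell, cells)
        cell <- modulate_period(cell, dens, config$quorum_table)
      }
      return(list(cell = cell, mode = "REVERSED", direction = NULL,
                  angle = NA_real_))
    }
  } else {
    cell$phase <- cell$phase + config$dt
  }
  # (b) collision
  hit <- detect_collision(cell, cells)
  if (!is.null(hit)) {
    if (hit$node == 1L) {
      out <- resolve_pole_to_pole(cell, config)
      return(list(cell = out$cell, mode = "COLLISION_POLE",
                  direction = out$direction, angle = out$angle))
    }
    partner <- Filter(function(x) x$id == hit$partner, cells)[[1]]
    dir <- resolve_pole_to_side(cell, partner)
    return(list(cell = cell, mode = "COLLISION_ALIGN", direction = dir,
                angle = NA_real_))
  }
  # (c) EPS trail following
  if (config$eps && !is.null(field)) {
    dir <- eps_direction(field, cell, radius = config$sense_radius,
                         exclude = exclude,
                         n_sectors = config$n_sectors,
                         contrast = config$eps_contrast)
    if (!is.null(dir)) {
      return(list(cell = cell, mode = "EPS_FOLLOW", direction = dir,
                  angle = NA_real_))
    }
  }
  # (d) active turning
  if (config$turning) {
    tn <- check_active_turn(cell, now, config)
    cell <- tn$cell
    if (!is.null(tn$direction)) {
      return(list(cell = cell, mode = "ACTIVE_TURN",
                  direction = tn$direction, angle = tn$angle))
    }
  }
  list(cell = cell, mode = "STRAIGHT",
       direction = cell_orientation(cell), angle = NA_real_)
}

#' Move a cell one step along a decided direction
#'
#' The leading pole advances `speed * dt` along the direction; the body
#' nodes are repositioned along the recorded leading-pole track at
#' arc-length spacing L, preserving the equal-segment invariant. A reversal
#' outcome (`direction = NULL`) does not translate the cell.
#'
#' @param cell a `myxo_cell`.
#' @param direction unit 2-vector, or `NULL` for a reversal step.
#' @param dt time step (min).
#' @return The updated cell.
#' @export
advance <- function(cell, direction, dt) {
  if (is.null(direction)) return(cell)
  nrm <- sqrt(sum(direction^2))
  if (abs(nrm - 1) > 1e-6) stop("direction must be a unit vector")
  pole <- cell$track[nrow(cell$track), ]
  newp <- pole + direction * cell$speed * dt
  cell$track <- rbind(cell$track, newp)
  # prune waypoints no longer needed to span one body length
  cum <- c(0, cumsum(sqrt(rowSums(diff(cell$track)^2))))
  while (nrow(cell$track) > 2 &&
         cum[length(cum)] - cum[2] > cell$length + 1e-9) {
    cell$track <- cell$track[-1, , drop = FALSE]
    cum <- cum[-1]
  }
  cell$nodes_u <- place_on_track_cpp(cell$track, cell$n_nodes, cell$seg_len)
  cell$nodes <- wrap_position(cell$nodes_u, cell$domain)
  cell
}

# internal: pack a list of cells into the padded node matrix layout
cells_to_matrix <- function(cells) {
  n <- length(cells)
  nodes <- matrix(NA_real_, n, 10)
  nn <- integer(n)
  for (i in seq_len(n)) {
    m <- cells[[i]]$n_nodes
    nn[i] <- m
    nodes[i, seq_len(2 * m)] <- t(cells[[i]]$nodes)
  }
  list(nodes = nodes, n_nodes = nn)
}

#' @export
print.myxo_cell <- function(x, ...) {
  o <- cell_orientation(x)
  cat(sprintf(
    "<myxo_cell %d> %d nodes, length %.2f um, pole (%.2f, %.2f), heading %.0f deg\n",
    x$id, x$n_nodes, x$length, x$nodes[1, 1], x$nodes[1, 2],
    atan2(o[2], o[1]) * 180 / pi))
  invisible(x)
}
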