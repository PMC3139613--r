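#' Initialize a colony
#'
#' Places `n_cells` straight cells uniformly at random with uniform random
#' orientations over the periodic domain, samples per-cell parameters, sets
#' every reversal clock to a random phase between 0 and the cell's period,
#' and creates an empty slime field.
#'
#' @param config a [myxo_config()].
#' @param seed integer seed; the same seed and configuration reproduce the
#'   initial state and the subsequent trajectory exactly.
#' @return A `myxo_state` list holding the packed cell matrices, the slime
#'   field, the configuration, the seed, and the step/time counters.
#' @export
initialize_colony <- function(config = myxo_preset("WT_LOW"), seed = 1L) {
  stopifnot(inherits(config, "myxo_config"))
  set.seed(as.integer(seed))
  n <- config$n_cells
  par <- sample_cell_params(n, config)
  pole <- cbind(runif(n, 0, config$width), runif(n, 0, config$height))
  ang <- runif(n, 0, 2 * pi)
  dir <- cbind(cos(ang), sin(ang))

  nodes <- matrix(NA_real_, n, 10)
  for (k in 0:4) {
    active <- par$n_nodes > k
    nodes[active, 2 * k + 1] <- pole[active, 1] -
      k * par$seg_len[active] * dir[active, 1]
    nodes[active, 2 * k + 2] <- pole[active, 2] -
      k * par$seg_len[active] * dir[active, 2]
  }
  nodes[, seq(1, 9, 2)] <- nodes[, seq(1, 9, 2)] %% config$width
  nodes[, seq(2, 10, 2)] <- nodes[, seq(2, 10, 2)] %% config$height

  field <- slime_field(config, config$bin_size, config$deposit_rate)
  state <- list(
    nodes = nodes,
    n_nodes = par$n_nodes,
    length = par$length,
    width = par$width,
    seg_len = par$seg_len,
    period_base = par$period,
    period_cur = par$period,
    phase = runif(n, 0, par$period),
    turn_interval = par$turn_interval,
    last_turn = rep(0, n),
    slime = field$counts,
    config = config,
    seed = as.integer(seed),
    step = 0L,
    time = 0
  )
  class(state) <- "myxo_state"
  state
}

# internal: state -> snapshot matrix (centroid x, y, orientation ox, oy)
state_snapshot <- function(state) {
  n <- nrow(state$nodes)
  cfg <- state$config
  out <- matrix(NA_real_, n, 4)
  for (i in seq_len(n)) {
    m <- state$n_nodes[i]
    ch <- matrix(state$nodes[i, seq_len(2 * m)], m, 2, byrow = TRUE)
    # unwrap chain around the leading pole for a consistent centroid
    u <- ch
    for (k in 2:m) {
      u[k, ] <- u[k - 1, ] + min_image_cpp(u[k - 1, , drop = FALSE],
                                           ch[k, , drop = FALSE],
                                           cfg$width, cfg$height)
    }
    o <- u[1, ] - u[m, ]
    o <- o / sqrt(sum(o^2))
    cen <- colMeans(u)
    out[i, ] <- c(cen[1] %% cfg$width, cen[2] %% cfg$height, o)
  }
  colnames(out) <- c("x", "y", "ox", "oy")
  out
}

#' Run a colony simulation
#'
#' Executes `hours * 60 / dt` steps of the motility algorithm. Per step:
#' the spatial index is rebuilt, every cell decides its mode from the
#' previous step's positions (synchronous read), all cells then move, and
#' moving EPS-producing cells deposit slime.
#'
#' @param state a `myxo_state` from [initialize_colony()].
#' @param hours simulated hours (default: the configuration's horizon).
#' @param snapshot_every snapshot cadence in simulated minutes (default
#'   from the configuration; `0` disables snapshots).
#' @param log_level event-log detail: 0 = none, 1 = reversals, collisions
#'   and active turns, 2 = additionally every EPS-follow event.
#' @param store_path keep the full node trajectory (memory-heavy; intended
#'   for small scenes).
#' @return A `myxo_sim` object: the final `state`, the `events` data frame
#'   (step, time, cell, mode, angle, density, period, moved), per-step
#'   `mode_counts` and `n_moved`, `snapshots` (list of n x 4 matrices) with
#'   `snapshot_times` (min), and the deposition ledger `total_deposited`.
#' @export
run_colony <- function(state, hours = NULL, snapshot_every = NULL,
                       log_level = 1L, store_path = FALSE) {
  stopifnot(inherits(state, "myxo_state"))
  cfg <- state$config
  if (is.null(hours)) hours <- cfg$hours
  if (is.null(snapshot_every)) snapshot_every <- cfg$snapshot_every
  n_steps <- sim_steps(hours, cfg$dt)
  snap_every <- if (snapshot_every > 0) {
    max(1L, as.integer(round(snapshot_every / cfg$dt)))
  } else {
    0L
  }

  snap0 <- state_snapshot(state)
  if (n_steps == 0) {
    res <- list(state = state, events = empty_events(),
                mode_counts = matrix(0L, 0, 6,
                                     dimnames = list(NULL, mode_names())),
                n_moved = integer(0),
                snapshots = list(snap0), snapshot_times = state$time,
                total_deposited = 0, config = cfg, seed = state$seed)
    class(res) <- "myxo_sim"
    return(res)
  }

  cstate <- list(
    nodes = state$nodes, n_nodes = as.integer(state$n_nodes),
    length = state$length, width = state$width, seg_len = state$seg_len,
    period_base = state$period_base, period_cur = state$period_cur,
    phase = state$phase, turn_interval = state$turn_interval,
    last_turn = state$last_turn, slime = state$slime
  )
  ccfg <- list(
    speed = cfg$speed, dt = cfg$dt, width = cfg$width, height = cfg$height,
    reversal_on = cfg$reversal, quorum_on = cfg$quorum,
    eps_on = cfg$eps, turning_on = cfg$turning,
    quorum_table = quorum_table_capped(cfg$quorum_table),
    deposit_rate = cfg$deposit_rate, n_sectors = cfg$n_sectors,
    eps_contrast = cfg$eps_contrast,
    sense_radius = if (is.null(cfg$sense_radius)) -1 else cfg$sense_radius,
    turn_mean = cfg$turn_mean, turn_sd = cfg$turn_sd,
    turn_max = cfg$turn_max,
    turn_interval_mean = cfg$turn_interval_mean,
    turn_interval_sd = cfg$turn_interval_sd,
    pass_min = cfg$pass_range[1], pass_max = cfg$pass_range[2]
  )
  # derive a fresh engine stream when resuming so draws are not replayed
  eng_seed <- (as.numeric(state$seed) * 1000003 + state$step) %% 2^31
  crun <- list(
    n_steps = as.integer(n_steps), step0 = state$step, t0 = state$time,
    seed = eng_seed, snap_every = snap_every,
    log_level = as.integer(log_level), store_path = isTRUE(store_path)
  )
  out <- engine_run_cpp(cstate, ccfg, crun)

  state$nodes <- out$nodes
  state$period_cur <- out$period_cur
  state$phase <- out$phase
  state$turn_interval <- out$turn_interval
  state$last_turn <- out$last_turn
  state$slime <- out$slime
  state$step <- state$step + n_steps
  state$time <- state$time + n_steps * cfg$dt

  ev <- as.data.frame(out$events)
  ev$mode <- factor(mode_names()[ev$mode], levels = mode_names())
  ev$cell <- as.integer(ev$cell)
  ev$step <- as.integer(ev$step)

  n <- cfg$n_cells
  snaps <- list(snap0)
  times <- state$time - n_steps * cfg$dt
  if (length(out$snap_steps) > 0) {
    for (s in seq_along(out$snap_steps)) {
      m <- out$snapshots[seq((s - 1) * n + 1, s * n), , drop = FALSE]
      colnames(m) <- c("x", "y", "ox", "oy")
      snaps <- c(snaps, list(m))
    }
    times <- c(times, out$snap_steps * cfg$dt)
  }

  mc <- out$mode_counts
  colnames(mc) <- mode_names()

  res <- list(state = state, events = ev, mode_counts = mc,
              n_moved = out$n_moved, snapshots = snaps,
              snapshot_times = times,
              total_deposited = out$total_deposited,
              config = cfg, seed = state$seed)
  if (store_path) res$path <- out$path
  class(res) <- "myxo_sim"
  res
}

#' Initialize and run in one call
#'
#' @inheritParams initialize_colony
#' @inheritParams run_colony
#' @param ... passed to [run_colony()].
#' @return A `myxo_sim`, see [run_colony()].
#' @examples
#' cfg <- myxo_config(n_cells = 20, width = 60, hours = 0.5)
#' sim <- simulate_colony(cfg, seed = 7)
#' table(sim$events$mode)
#' @export
simulate_colony <- function(config = myxo_preset("WT_LOW"), seed = 1L,
                            hours = NULL, ...) {
  run_colony(initialize_colony(config, seed), hours = hours, ...)
}

mode_names <- function() {
  c("REVERSED", "COLLISION_ALIGN", "COLLISION_POLE", "EPS_FOLLOW",
    "ACTIVE_TURN", "STRAIGHT")
}

empty_events <- function() {
  data.frame(step = integer(0), time_min = numeric(0), cell = integer(0),
             mode = factor(character(0), levels = mode_names()),
             angle_deg = numeric(0), density = numeric(0),
             period_min = numeric(0), moved = numeric(0))
}

# internal: replace Inf bounds so the engine can draw uniformly
quorum_table_capped <- function(tab, cap = 360) {
  tab[, "phi"] <- pmin(tab[, "phi"], cap)
  tab
}

#' @export
print.myxo_sim <- function(x, ...) {
  cat("<myxo_sim>\n")
  cat(sprintf("  %d cells, %g x %g um, %d steps (%.2f h simulated)\n",
              x$config$n_cells, x$config$width, x$config$height,
              x$state$step, x$state$time / 60))
  if (nrow(x$events) > 0) {
    tb <- table(x$events$mode)
    tb <- tb[tb > 0]
    cat("  logged events:",
        paste(sprintf("%s=%d", names(tb), as.integer(tb)), collapse = ", "),
        "\n")
  }
  cat(sprintf("  slime total %d, %d snapshots\n", sum(x$state$slime),
              length(x$snapshots)))
  invisible(x)
}
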