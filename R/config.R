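#' Quorum-sensing lookup table
#'
#' Density classes mapping local neighbor counts to reversal-period ranges
#' (minutes). At each polarity reversal the cell counts neighbors inside its
#' square measuring domain (side = one cell length); if the count falls in a
#' class, a new reversal period is drawn uniformly from that class's range,
#' otherwise the cell falls back to its baseline sampled period. The
#' open-ended highest class is capped at 360 min, which is longer than any
#' simulated run and therefore behaviorally non-reversing.
#'
#' @return A numeric matrix with columns `dlo`, `dhi` (neighbor-count range)
#'   and `plo`, `phi` (reversal-period range, minutes).
#' @export
default_quorum_table <- function() {
  tab <- rbind(
    c(5,    19,   8,  12),
    c(20,   99,  15,  30),
    c(100,  999, 30,  40),
    c(1000, Inf, 300, 360)
  )
  colnames(tab) <- c("dlo", "dhi", "plo", "phi")
  tab
}

#' Simulation configuration
#'
#' Assembles the full parameter set of the model. Defaults are the
#' experimentally determined wild-type values: cell length uniform on
#' 3-5 um with width 0.1 of length, gliding speed 4.5 um/min, time step
#' 1/3 min, baseline reversal period Normal(6.24, 0.5) min, active-turning
#' angle Normal(30, 10) degrees truncated to (0, 90] with equal left/right
#' probability, and active-turning interval Normal(3, 1) min.
#'
#' @param n_cells number of cells.
#' @param width,height domain size (um); boundaries are always periodic.
#' @param dt time step (min).
#' @param length_range cell length sampling range (um); the node count is
#'   `round(length)` clamped to 3-5 so segments are about 1-2 um.
#' @param speed gliding speed (um/min).
#' @param width_ratio cell width as a fraction of cell length.
#' @param reversal enable the polarity-reversal clock.
#' @param reversal_mean,reversal_sd baseline reversal-period distribution
#'   (min), truncated at 0.1 min.
#' @param quorum enable density-dependent reversal-period modulation.
#' @param quorum_table see [default_quorum_table()].
#' @param eps enable EPS slime deposition and trail following.
#' @param deposit_rate EPS points deposited per moving cell per step.
#' @param bin_size slime lattice bin size (um).
#' @param n_sectors angular sectors splitting the forward semicircle for
#'   trail following.
#' @param eps_contrast minimum factor by which the winning sector's count
#'   must exceed the mean count of the other sectors for the cell to be
#'   redirected; in near-uniform slime no direction of higher concentration
#'   exists and the cell is not redirected. `0` disables the condition.
#' @param sense_radius slime sensing radius (um); `NULL` uses each cell's
#'   own length (approximately one type-IV pilus length).
#' @param turning enable active turning.
#' @param turn_mean,turn_sd,turn_max active-turning angle distribution
#'   (degrees): Normal(mean, sd) truncated to (0, max], sign uniform.
#' @param turn_interval_mean,turn_interval_sd active-turning interval
#'   distribution (min), truncated at 0.1 min.
#' @param pass_range magnitude range (degrees) of the slight random turn
#'   used to pass by in a pole-to-pole collision.
#' @param hours default simulated horizon (h).
#' @param snapshot_every snapshot cadence (simulated min).
#' @return An object of class `myxo_config` (a named list).
#' @seealso [myxo_preset()], [scale_preset()], [simulate_colony()]
#' @export
myxo_config <- function(n_cells = 100, width = 100, height = width,
                        dt = 1 / 3,
                        length_range = c(3, 5), speed = 4.5,
                        width_ratio = 0.1,
                        reversal = TRUE, reversal_mean = 6.24,
                        reversal_sd = 0.5,
                        quorum = TRUE, quorum_table = default_quorum_table(),
                        eps = TRUE, deposit_rate = 1L, bin_size = 0.5,
                        n_sectors = 6L, eps_contrast = 2, sense_radius = NULL,
                        turning = TRUE, turn_mean = 30, turn_sd = 10,
                        turn_max = 90,
                        turn_interval_mean = 3, turn_interval_sd = 1,
                        pass_range = c(10, 30),
                        hours = 2, snapshot_every = 15) {
  stopifnot(n_cells >= 1, width > 0, height > 0, dt > 0, speed > 0,
            length_range[1] > 0, diff(length_range) >= 0,
            reversal_mean > 0, turn_interval_mean > 0,
            turn_max > 0, bin_size > 0)
  cfg <- list(
    n_cells = as.integer(n_cells), width = width, height = height, dt = dt,
    length_range = length_range, speed = speed, width_ratio = width_ratio,
    reversal = isTRUE(reversal), reversal_mean = reversal_mean,
    reversal_sd = reversal_sd,
    quorum = isTRUE(quorum), quorum_table = quorum_table,
    eps = isTRUE(eps), deposit_rate = as.integer(deposit_rate),
    bin_size = bin_size, n_sectors = as.integer(n_sectors),
    eps_contrast = eps_contrast,
    sense_radius = sense_radius,
    turning = isTRUE(turning), turn_mean = turn_mean, turn_sd = turn_sd,
    turn_max = turn_max,
    turn_interval_mean = turn_interval_mean,
    turn_interval_sd = turn_interval_sd,
    pass_range = pass_range,
    hours = hours, snapshot_every = snapshot_every
  )
  class(cfg) <- "myxo_config"
  cfg
}

#' Experiment presets
#'
#' Named parameter sets for the wild-type and mutant experiments.
#'
#' * `WT_LOW` - 100 wild-type cells, 100 x 100 um, 2 h: the low-density
#'   gliding-pattern experiment.
#' * `WT_DEV` - 5000 wild-type cells, 141 x 141 um, 12 h: developmental
#'   aggregation with all five behavioral rules. The density (~0.25
#'   cells/um^2, 40 percent monolayer coverage) is the regime in which the
#'   quorum-sensing ladder engages: streams reach the 20-99 neighbor class
#'   and centers go beyond, as the quorum table presupposes.
#' * `ANGLE_SWEEP` - `WT_DEV` with a configurable mean turning angle and a
#'   20 h horizon.
#' * `SW504` - EPS-null mutant: no slime deposition or following.
#' * `SW600` - hypo-reversing mutant: fixed 120 min reversal period,
#'   quorum sensing off.
#' * `SW601` - hyper-reversing mutant: 2 min reversal period, quorum
#'   sensing off.
#' * `ISOLATED` - 200 cells on a 2000 x 2000 um surface with EPS and
#'   quorum sensing off: the single-cell motility measurement harness used
#'   to recover reversal and turning statistics.
#'
#' Mutant presets differ from `WT_DEV` only in the parameters named above.
#'
#' @param name preset name.
#' @param turn_mean mean active-turning angle override (degrees), used by
#'   `ANGLE_SWEEP`.
#' @return A `myxo_config`.
#' @export
myxo_preset <- function(name = c("WT_LOW", "WT_DEV", "ANGLE_SWEEP", "SW504",
                                 "SW600", "SW601", "ISOLATED"),
                        turn_mean = 30) {
  name <- match.arg(name)
  switch(name,
    WT_LOW = myxo_config(n_cells = 100, width = 100, hours = 2),
    WT_DEV = myxo_config(n_cells = 5000, width = 141, hours = 12),
    ANGLE_SWEEP = myxo_config(n_cells = 5000, width = 141, hours = 20,
                              turn_mean = turn_mean),
    SW504 = myxo_config(n_cells = 5000, width = 141, hours = 12,
                        eps = FALSE),
    SW600 = myxo_config(n_cells = 5000, width = 141, hours = 12,
                        reversal_mean = 120, quorum = FALSE),
    SW601 = myxo_config(n_cells = 5000, width = 141, hours = 12,
                        reversal_mean = 2, quorum = FALSE),
    ISOLATED = myxo_config(n_cells = 200, width = 2000, hours = 2,
                           eps = FALSE, quorum = FALSE)
  )
}

#' Scale a configuration down (or up) at constant number density
#'
#' Multiplies the cell count and the domain area by `factor` so that the
#' number density (cells/um^2) is preserved; behavioral parameters are
#' untouched. Used to run the developmental experiments at desk scale.
#'
#' @param config a `myxo_config`.
#' @param factor scale factor in (0, 1].
#' @return The scaled `myxo_config`.
#' @export
scale_preset <- function(config, factor) {
  stopifnot(inherits(config, "myxo_config"), factor > 0, factor <= 1)
  config$n_cells <- max(1L, as.integer(round(config$n_cells * factor)))
  config$width <- config$width * sqrt(factor)
  config$height <- config$height * sqrt(factor)
  config
}

#' Number of simulation steps for a horizon
#'
#' @param hours simulated hours.
#' @param dt time step (min), default 1/3.
#' @return Integer step count, `hours * 60 / dt`.
#' @export
sim_steps <- function(hours, dt = 1 / 3) {
  as.integer(round(hours * 60 / dt))
}

#' @export
print.myxo_config <- function(x, ...) {
  cat("<myxo_config>\n")
  cat(sprintf("  %d cells in %g x %g um, dt = %.4g min, horizon %g h\n",
              x$n_cells, x$width, x$height, x$dt, x$hours))
  cat(sprintf("  reversal: %s (T ~ N(%g, %g) min), quorum: %s\n",
              x$reversal, x$reversal_mean, x$reversal_sd, x$quorum))
  cat(sprintf("  EPS: %s (bin %g um, rate %d), turning: %s (N(%g, %g) deg)\n",
              x$eps, x$bin_size, x$deposit_rate, x$turning, x$turn_mean,
              x$turn_sd))
  invisible(x)
}

# internal: domain accessor
as_domain <- function(x) {
  if (inherits(x, "myxo_config")) {
    list(width = x$width, height = x$height, dt = x$dt)
  } else if (is.list(x) && all(c("width", "height") %in% names(x))) {
    x
  } else if (is.numeric(x) && length(x) == 2) {
    list(width = x[1], height = x[2], dt = 1 / 3)
  } else {
    stop("cannot interpret domain specification")
  }
}
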