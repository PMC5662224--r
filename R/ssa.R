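#' @useDynLib circuitnoise, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Simulation configuration
#'
#' @param duration Simulated time in minutes (default 101,000 as in the
#'   full-length runs; tests and examples use much shorter durations).
#' @param record_interval Minutes between recorded state snapshots
#'   (default 1).
#' @param burn_in Minutes excluded from downstream statistics (default
#'   1,000; equilibration takes a few hundred minutes).
#' @param seed Integer RNG seed for the simulation stream.
#' @return An object of class \code{sim_config}.
#' @export
sim_config <- function(duration = 101000, record_interval = 1,
                       burn_in = 1000, seed = 1L) {
  if (duration <= burn_in) stop("duration must exceed burn_in")
  if (record_interval <= 0) stop("record_interval must be > 0")
  structure(list(duration = duration, record_interval = record_interval,
                 burn_in = burn_in, seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a circuit trajectory with the exact stochastic simulation
#' algorithm
#'
#' Runs an exact SSA realisation of a [build_network()] circuit.  All
#' internal kinetics are in seconds (the rate units); the public grid is in
#' minutes.  When an extrinsic series is supplied, every translation
#' reaction's propensity is multiplied by the series value for the current
#' recording interval — piecewise-constant coupling on the 1-min grid,
#' which is a fine discretisation relative to the 200-min extrinsic
#' relaxation time.
#'
#' @param network A \code{network_spec}.
#' @param config A [sim_config()].
#' @param extrinsic An [extrinsic_series()] (or plain numeric vector of
#'   per-interval factors), or \code{NULL} for no extrinsic noise.
#' @return An object of class \code{trajectory}: \code{time} (minutes),
#'   \code{counts} (matrix, one column per species), \code{extrinsic}
#'   (factor per grid point; 1 when off), plus the network and config.
#' @export
#' @examples
#' net <- build_network("constitutive")
#' tr <- simulate_circuit(net, sim_config(duration = 500, burn_in = 100, seed = 1))
#' mean(tr$counts[, "M1"])
simulate_circuit <- function(network, config, extrinsic = NULL) {
  .run_ssa(network, config, extrinsic,
           schedule_min = numeric(0), schedule_counts = integer(0))
}

#' Simulate with a stepwise inducer schedule
#'
#' Identical to [simulate_circuit()] except the free-inducer count is reset
#' to given values at given times — the in-silico analogue of stepping the
#' inducer concentration up and washing it out.  Only fast inducer mode is
#' supported: in slow mode the conserved-pool semantics of an externally
#' imposed step are ambiguous, and such schedules are rejected.
#'
#' @param network A \code{network_spec} with \code{inducer_mode = "fast"}.
#' @param config A [sim_config()].
#' @param schedule A data.frame with columns \code{time} (minutes,
#'   increasing, multiples of the record interval) and \code{inducer}
#'   (counts).  A step to 0 emulates an inducer wash.
#' @param extrinsic As in [simulate_circuit()].
#' @return A \code{trajectory}.
#' @export
simulate_schedule <- function(network, config, schedule, extrinsic = NULL) {
  stopifnot(is.data.frame(schedule),
            all(c("time", "inducer") %in% names(schedule)))
  if (network$inducer_mode != "fast")
    stop("inducer schedules require fast inducer mode (slow-mode pool semantics are ambiguous)")
  if (is.unsorted(schedule$time, strictly = TRUE))
    stop("schedule times must be strictly increasing")
  if (any(schedule$time < 0) || any(schedule$time > config$duration))
    stop("schedule times must lie within [0, duration]")
  if (any(schedule$inducer < 0)) stop("inducer counts must be >= 0")
  if (nrow(schedule) > 0 && schedule$time[1] == 0) {
    network$init["I"] <- as.integer(round(schedule$inducer[1]))
    network$inducer <- network$init[["I"]]
  }
  .run_ssa(network, config, extrinsic,
           schedule_min = schedule$time,
           schedule_counts = as.integer(round(schedule$inducer)))
}

.run_ssa <- function(network, config, extrinsic, schedule_min,
                     schedule_counts) {
  stopifnot(inherits(network, "network_spec"), inherits(config, "sim_config"))
  rec_sec <- config$record_interval * 60
  t_end <- config$duration * 60
  n_intervals <- floor(t_end / rec_sec + 1e-9)

  if (is.null(extrinsic)) {
    factors <- rep(1.0, n_intervals)
    extr_pts <- rep(1.0, n_intervals + 1)
  } else {
    factors <- if (inherits(extrinsic, "extrinsic_series"))
      extrinsic$factor else as.numeric(extrinsic)
    if (length(factors) < n_intervals + 1)
      stop("extrinsic series too short: need ", n_intervals + 1,
           " grid points, got ", length(factors))
    extr_pts <- factors[seq_len(n_intervals + 1)]
    factors <- factors[seq_len(n_intervals)]
  }

  counts <- ssa_run_cpp(network$init, network$reactants, network$net,
                        network$rates_vec, network$is_translation,
                        t_end, rec_sec, factors, config$seed,
                        schedule_min * 60, schedule_counts,
                        which(network$species == "I") - 1L)
  colnames(counts) <- network$species
  structure(list(
    time = seq(0, config$duration, by = config$record_interval),
    counts = counts,
    extrinsic = extr_pts,
    network = network,
    config = config
  ), class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat("<trajectory>", x$network$scheme, "|", length(x$time), "points,",
      x$config$duration, "min\n")
  invisible(x)
}
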