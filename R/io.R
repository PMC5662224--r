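#' Write a trajectory to TSV with a JSON sidecar
#'
#' The TSV holds the time column (minutes), one column per species, and
#' the extrinsic factor; a \code{<path>.json} sidecar stores the network
#' and configuration so the pair round-trips losslessly.
#'
#' @param trajectory A [simulate_circuit()] trajectory.
#' @param path Output TSV path.
#' @return \code{path}, invisibly.
#' @export
write_trajectory <- function(trajectory, path) {
  stopifnot(inherits(trajectory, "trajectory"))
  d <- data.frame(time = trajectory$time, trajectory$counts,
                  extrinsic = trajectory$extrinsic,
                  check.names = FALSE)
  utils::write.table(d, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  net <- trajectory$network
  side <- list(
    scheme = net$scheme,
    rates = unclass(net$rates),
    n_dna1 = net$n_dna1, n_dna2 = net$n_dna2,
    inducer = net$inducer, inducer_mode = net$inducer_mode,
    config = unclass(trajectory$config))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a trajectory written by [write_trajectory()]
#'
#' @param path TSV path (the \code{<path>.json} sidecar must be present).
#' @return A \code{trajectory}.
#' @export
read_trajectory <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         check.names = FALSE)
  side <- jsonlite::read_json(paste0(path, ".json"),
                              simplifyVector = TRUE)
  net <- build_network(side$scheme, do.call(rate_set, as.list(side$rates)),
                       n_dna1 = side$n_dna1, n_dna2 = side$n_dna2,
                       inducer = side$inducer,
                       inducer_mode = side$inducer_mode)
  cfg <- sim_config(duration = side$config$duration,
                    record_interval = side$config$record_interval,
                    burn_in = side$config$burn_in,
                    seed = side$config$seed)
  counts <- as.matrix(d[, net$species, drop = FALSE])
  structure(list(time = d$time, counts = counts,
                 extrinsic = d$extrinsic, network = net, config = cfg),
            class = "trajectory")
}

#' Write / read an extrinsic series as CSV with a JSON sidecar
#'
#' Single-column CSV of factors plus a \code{<path>.json} sidecar with the
#' OU parameters, so one realisation can be reused across circuit schemes
#' for paired comparisons.
#'
#' @param series An [extrinsic_series()].
#' @param path Output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_extrinsic <- function(series, path) {
  stopifnot(inherits(series, "extrinsic_series"))
  utils::write.csv(data.frame(factor = series$factor), path,
                   row.names = FALSE)
  if (!is.null(series$params))
    jsonlite::write_json(unclass(series$params), paste0(path, ".json"),
                         auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_extrinsic
#' @export
read_extrinsic <- function(path) {
  d <- utils::read.csv(path)
  side <- paste0(path, ".json")
  params <- if (file.exists(side)) {
    p <- jsonlite::read_json(side, simplifyVector = TRUE)
    ou_params(tau = p$tau, c = p$c, dt = p$dt, seed = p$seed,
              c_units = p$c_units)
  } else NULL
  structure(list(factor = d$factor, params = params),
            class = "extrinsic_series")
}

#' Write a dose-response curve and its run manifest
#'
#' Tidy CSV (scheme, inducer, replicate, mean, var, noise) plus a JSON
#' manifest capturing the generating configuration for reproducibility.
#'
#' @param curve A [dose_response()] result.
#' @param path Output CSV path.
#' @param manifest Named list of run metadata (seeds, grids, parameters)
#'   written to \code{<path>.json}.
#' @return \code{path}, invisibly.
#' @export
write_curve <- function(curve, path, manifest = list()) {
  utils::write.csv(as.data.frame(curve), path, row.names = FALSE)
  manifest$extrinsic <- attr(curve, "extrinsic")
  manifest$inducer_mode <- attr(curve, "inducer_mode")
  jsonlite::write_json(manifest, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a flow-cytometry event table from CSV
#'
#' Expects a header with at least \code{FSCA,SSCH,FL1A}.
#'
#' @param path CSV path.
#' @return data.frame of events.
#' @export
read_events <- function(path) {
  d <- utils::read.csv(path)
  .check_events(d)
  if (!"FL1A" %in% names(d)) stop("event table lacks column FL1A")
  d
}
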