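#' Fit single-molecule spot intensities to a gamma distribution
#'
#' Maximum-likelihood gamma fit of detected single-fluorophore spot
#' intensities; the fitted mean (shape x scale) is the counts-per-molecule
#' calibration at the imaging condition under which the spots were
#' acquired.
#'
#' @param intensities Positive spot intensities (counts).  Fewer than 50
#'   values triggers a small-sample warning.
#' @return Object of class \code{gamma_calibration}: \code{shape},
#'   \code{scale}, \code{mean}, standard errors, \code{n}.
#' @export
fit_gamma_spots <- function(intensities) {
  if (any(!is.finite(intensities)) || any(intensities <= 0))
    stop("spot intensities must be positive and finite")
  n <- length(intensities)
  if (n < 50)
    warning("only ", n, " spots; calibration will have wide confidence intervals")
  if (stats::sd(intensities) < 1e-12 * mean(intensities)) {
    warning("degenerate (near-constant) intensities; shape is unbounded")
    return(structure(list(shape = Inf, scale = 0,
                          mean = mean(intensities),
                          se = c(shape = NA_real_, rate = NA_real_),
                          n = n), class = "gamma_calibration"))
  }
  # fit on unit-mean rescaled data for numerical stability, then rescale
  m0 <- mean(intensities)
  f <- fitdistrplus::fitdist(as.numeric(intensities) / m0, "gamma",
                             method = "mle")
  shape <- f$estimate[["shape"]]
  rate <- f$estimate[["rate"]] / m0
  se <- f$sd
  se[["rate"]] <- se[["rate"]] / m0
  structure(list(shape = shape, scale = 1 / rate, mean = shape / rate,
                 se = se, n = n),
            class = "gamma_calibration")
}

#' @export
print.gamma_calibration <- function(x, ...) {
  cat(sprintf("<gamma_calibration> mean %.4g counts/molecule (shape %.3g, scale %.4g, n = %d)\n",
              x$mean, x$shape, x$scale, x$n))
  invisible(x)
}

#' Imaging condition (integration time and laser power)
#'
#' @param integration_ms Camera integration time in milliseconds (> 0).
#' @param power Laser power fraction (1.0 = 100%, > 0).
#' @return Object of class \code{imaging_condition}.
#' @export
imaging_condition <- function(integration_ms, power) {
  if (integration_ms <= 0 || power <= 0)
    stop("integration time and power must be > 0")
  structure(list(integration_ms = integration_ms, power = power),
            class = "imaging_condition")
}

#' Rescale a single-molecule calibration between imaging conditions
#'
#' In vivo fluorescence intensity is linear in both integration time and
#' laser power, so the counts-per-molecule calibration transfers between
#' conditions by the product of their ratios.
#'
#' @param cal A \code{gamma_calibration} or a plain mean intensity
#'   (counts per molecule).
#' @param from,to [imaging_condition()]s.
#' @return Mean counts per molecule at the target condition.
#' @export
#' @examples
#' scale_calibration(3669, imaging_condition(17.5, 1), imaging_condition(35, 0.15))
scale_calibration <- function(cal, from, to) {
  stopifnot(inherits(from, "imaging_condition"),
            inherits(to, "imaging_condition"))
  m <- if (inherits(cal, "gamma_calibration")) cal$mean else as.numeric(cal)
  m * (to$integration_ms / from$integration_ms) * (to$power / from$power)
}

#' Estimate molecules per cell from integrated fluorescence
#'
#' @param cells Either a numeric vector of integrated background-subtracted
#'   fluorescence values (counts) or a data.frame with column
#'   \code{integrated_counts} (and optionally \code{area}).
#' @param counts_per_molecule Calibration (counts per single fluorophore,
#'   > 0), typically from [fit_gamma_spots()] via [scale_calibration()].
#' @return Numeric vector of molecules per cell.
#' @export
estimate_molecules <- function(cells, counts_per_molecule) {
  if (counts_per_molecule <= 0) stop("counts_per_molecule must be > 0")
  counts <- if (is.data.frame(cells)) cells$integrated_counts else cells
  if (is.null(counts)) stop("cells must supply 'integrated_counts'")
  as.numeric(counts) / counts_per_molecule
}

#' Normalise molecule counts for cell size
#'
#' Divides each cell's molecule count by its area and multiplies by the
#' mean area, removing the component of cell-to-cell variability explained
#' by cell size (area is approximately proportional to volume for
#' rod-shaped bacteria).
#'
#' @param molecules Molecules per cell.
#' @param areas Cell areas, one per cell (> 0).
#' @return Size-normalised molecules per cell.
#' @export
size_normalize <- function(molecules, areas) {
  if (length(molecules) != length(areas))
    stop("molecules and areas must match one-to-one")
  if (any(areas <= 0)) stop("areas must be > 0")
  molecules / areas * mean(areas)
}
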