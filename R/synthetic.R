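#' Ground truth for synthetic flow-cytometry data
#'
#' Describes the generative model for [synth_cytometry()]: in-gate cells
#' carry fluorescence equal to an autofluorescence background draw plus a
#' log-normal expression draw; debris events (out of gate) carry
#' background only.  The scatter cloud is a tight 2D log-normal around the
#' peak for cells and a broad, displaced cloud for debris, so that the
#' standard scatter gate keeps approximately the cell fraction.
#'
#' @param meanlog,sdlog Log-normal expression parameters.
#' @param background_mean Autofluorescence background level (default 191
#'   counts).
#' @param background_sd Background spread; 0 gives a constant background
#'   (point mass).
#' @param peak_FSCA,peak_SSCH Scatter-peak coordinates.
#' @param cell_scatter_sdlog Log-scale scatter spread of intact cells
#'   (small: well inside the gate).
#' @param debris_frac Fraction of events that are debris (default 2/3, so
#'   roughly one third of events pass the gate).
#' @param n_events Number of events (default 30,000).
#' @param seed RNG seed.
#' @return Object of class \code{cytometry_truth}.
#' @export
cytometry_truth <- function(meanlog = log(500), sdlog = 0.25,
                            background_mean = 191, background_sd = 0,
                            peak_FSCA = 1e4, peak_SSCH = 1e3,
                            cell_scatter_sdlog = 0.07,
                            debris_frac = 2 / 3,
                            n_events = 30000, seed = 1L) {
  stopifnot(sdlog > 0, n_events >= 1, debris_frac >= 0, debris_frac < 1,
            background_sd >= 0, background_mean >= 0)
  structure(as.list(environment()), class = "cytometry_truth")
}

#' Generate a synthetic flow-cytometry event table
#'
#' @param truth A [cytometry_truth()].
#' @return data.frame with columns \code{FSCA}, \code{SSCH}, \code{FL1A}
#'   and logical \code{is_cell}; attribute \code{truth} stores the
#'   generator parameters.
#' @export
#' @examples
#' ev <- synth_cytometry(cytometry_truth(n_events = 2000, seed = 3))
#' mean(ev$is_cell)
synth_cytometry <- function(truth) {
  stopifnot(inherits(truth, "cytometry_truth"))
  old <- .save_seed()
  on.exit(.restore_seed(old))
  set.seed(truth$seed)
  n <- truth$n_events
  is_cell <- stats::runif(n) >= truth$debris_frac
  n_cell <- sum(is_cell)

  fsca <- ssch <- numeric(n)
  # intact cells: tight log-normal cloud at the peak
  fsca[is_cell] <- truth$peak_FSCA *
    exp(stats::rnorm(n_cell, 0, truth$cell_scatter_sdlog))
  ssch[is_cell] <- truth$peak_SSCH *
    exp(stats::rnorm(n_cell, 0, truth$cell_scatter_sdlog))
  # debris: much weaker scatter, spread well outside the gate
  n_deb <- n - n_cell
  fsca[!is_cell] <- truth$peak_FSCA * 0.1 *
    exp(stats::rnorm(n_deb, 0, 0.45))
  ssch[!is_cell] <- truth$peak_SSCH * 0.1 *
    exp(stats::rnorm(n_deb, 0, 0.45))

  bg <- if (truth$background_sd > 0)
    stats::rnorm(n, truth$background_mean, truth$background_sd)
  else rep(truth$background_mean, n)
  fl1a <- bg
  fl1a[is_cell] <- fl1a[is_cell] +
    stats::rlnorm(n_cell, truth$meanlog, truth$sdlog)

  out <- data.frame(FSCA = fsca, SSCH = ssch, FL1A = fl1a,
                    is_cell = is_cell)
  attr(out, "truth") <- truth
  out
}

#' Ground truth for synthetic microscopy data
#'
#' @param mol_mean Mean molecules per cell of the expression distribution.
#' @param mol_noise Expression noise (CV^2) of molecules per cell.
#' @param area_sdlog Log-scale spread of the (unit-mean) cell-area
#'   distribution.
#' @param counts_per_molecule Fluorescence calibration (counts per
#'   molecule).
#' @param spot_shape,spot_scale Gamma parameters of single-molecule spot
#'   intensities.
#' @param background_sd Additive per-cell measurement noise (counts).
#' @param n_cells,n_spots Sample sizes (defaults 300 cells, 858 spots).
#' @param seed RNG seed.
#' @return Object of class \code{microscopy_truth}.
#' @export
microscopy_truth <- function(mol_mean = 300, mol_noise = 0.06,
                             area_sdlog = 0.2,
                             counts_per_molecule = 1101,
                             spot_shape = 4, spot_scale = 917.25,
                             background_sd = 0,
                             n_cells = 300, n_spots = 858, seed = 1L) {
  stopifnot(mol_mean >= 0, mol_noise >= 0, area_sdlog >= 0,
            counts_per_molecule > 0, spot_shape > 0, spot_scale > 0,
            n_cells >= 1, n_spots >= 1)
  structure(as.list(environment()), class = "microscopy_truth")
}

#' Generate synthetic microscopy data
#'
#' Spots are gamma-distributed single-molecule intensities.  Each cell
#' draws a unit-mean log-normal area and a log-normal expression level
#' (mean \code{mol_mean}, noise \code{mol_noise}); its molecule count
#' scales with relative area, and its integrated fluorescence is molecules
#' times the calibration plus optional Gaussian measurement noise.
#'
#' @param truth A [microscopy_truth()].
#' @return List with \code{spots} (numeric vector), \code{cells}
#'   (data.frame \code{integrated_counts}, \code{area},
#'   \code{molecules_true}), and \code{truth}.
#' @export
synth_microscopy <- function(truth) {
  stopifnot(inherits(truth, "microscopy_truth"))
  old <- .save_seed()
  on.exit(.restore_seed(old))
  set.seed(truth$seed)
  spots <- stats::rgamma(truth$n_spots, shape = truth$spot_shape,
                         scale = truth$spot_scale)
  area <- stats::rlnorm(truth$n_cells, -truth$area_sdlog^2 / 2,
                        truth$area_sdlog)
  if (truth$mol_mean > 0) {
    s2 <- log(1 + truth$mol_noise)
    expr <- stats::rlnorm(truth$n_cells,
                          log(truth$mol_mean) - s2 / 2, sqrt(s2))
  } else expr <- numeric(truth$n_cells)
  molecules <- expr * area / mean(area)
  counts <- molecules * truth$counts_per_molecule
  if (truth$background_sd > 0)
    counts <- counts + stats::rnorm(truth$n_cells, 0, truth$background_sd)
  list(spots = spots,
       cells = data.frame(integrated_counts = counts, area = area,
                          molecules_true = molecules),
       truth = truth)
}

#' Generate synthetic dose-response or decay curve data
#'
#' Fixture generator for [fit_hill()] and [fit_exp_decay()].  With
#' \code{noise = 0} the output is a deterministic evaluation of the curve
#' (the seed is unused); otherwise multiplicative log-normal noise of the
#' given coefficient of variation is applied.
#'
#' @param kind \code{"hill"} or \code{"decay"}.
#' @param params For \code{"hill"}: list with \code{y0}, \code{ymax},
#'   \code{K}, \code{n_h}, and dose range \code{d_min}, \code{d_max}.
#'   For \code{"decay"}: list with \code{A}, \code{t_half}, \code{offset},
#'   and time range \code{t_max}.
#' @param noise Multiplicative noise CV (default 0).
#' @param n Number of points (default 12).
#' @param seed RNG seed (used only when \code{noise > 0}).
#' @return data.frame with columns \code{x}, \code{y}.
#' @export
synth_curve_data <- function(kind = c("hill", "decay"), params,
                             noise = 0, n = 12, seed = 1L) {
  kind <- match.arg(kind)
  stopifnot(is.list(params), n >= 2, noise >= 0)
  if (kind == "hill") {
    p <- utils::modifyList(list(y0 = 0, ymax = 1, K = 20, n_h = 1,
                                d_min = 0.1, d_max = 1000), params)
    x <- 10^seq(log10(p$d_min), log10(p$d_max), length.out = n)
    y <- p$y0 + (p$ymax - p$y0) * x^p$n_h / (p$K^p$n_h + x^p$n_h)
  } else {
    p <- utils::modifyList(list(A = 1000, t_half = 64.1, offset = 0,
                                t_max = 300), params)
    x <- seq(0, p$t_max, length.out = n)
    y <- p$A * 2^(-x / p$t_half) + p$offset
  }
  if (noise > 0) {
    old <- .save_seed()
    on.exit(.restore_seed(old))
    set.seed(seed)
    s2 <- log(1 + noise^2)
    y <- y * stats::rlnorm(n, -s2 / 2, sqrt(s2))
  }
  data.frame(x = x, y = y)
}
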