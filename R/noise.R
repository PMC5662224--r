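#' Summarise a trajectory into mean, variance and noise
#'
#' Noise is the squared coefficient of variation, variance divided by
#' squared mean, computed over the post-burn-in recorded samples.
#'
#' @param trajectory A [simulate_circuit()] trajectory.
#' @param species Species name (default \code{"P"}, the protein of
#'   interest).  May also be a vector of species whose counts are summed
#'   before summarising, e.g. \code{c("R", "RI")} for total repressor.
#' @param burn_in Minutes to discard (default: the trajectory's config).
#' @return Object of class \code{noise_summary}: \code{mean}, \code{var},
#'   \code{noise}, \code{n}, \code{species}.
#' @export
summarize_noise <- function(trajectory, species = "P", burn_in = NULL) {
  stopifnot(inherits(trajectory, "trajectory"))
  if (is.null(burn_in)) burn_in <- trajectory$config$burn_in
  if (burn_in >= max(trajectory$time))
    stop("trajectory shorter than burn_in")
  keep <- trajectory$time > burn_in
  bad <- setdiff(species, colnames(trajectory$counts))
  if (length(bad)) stop("unknown species: ", paste(bad, collapse = ", "))
  x <- if (length(species) == 1L) trajectory$counts[keep, species]
       else rowSums(trajectory$counts[keep, species, drop = FALSE])
  m <- mean(x)
  v <- stats::var(x)
  if (m == 0)
    stop("mean expression is zero; noise is undefined at this condition")
  structure(list(mean = m, var = v, noise = v / m^2, n = length(x),
                 species = paste(species, collapse = "+")),
            class = "noise_summary")
}

#' @export
print.noise_summary <- function(x, ...) {
  cat(sprintf("<noise_summary> %s: mean %.4g, var %.4g, noise (CV^2) %.4g, n = %d\n",
              x$species, x$mean, x$var, x$noise, x$n))
  invisible(x)
}

#' Intrinsic noise limit for unregulated expression
#'
#' For a constitutively expressed gene, protein noise cannot fall below
#' approximately \code{(1 + b) / mu}, where \code{b} is the burst size
#' (proteins per transcript, \code{kTL / deg_M}) and \code{mu} the mean
#' protein count.
#'
#' @param b Burst size (proteins per transcript), >= 0.
#' @param mu Mean protein count, > 0.
#' @return The limiting CV^2.
#' @export
#' @examples
#' intrinsic_limit(b = 0, mu = 100)  # Poisson limit, 0.01
intrinsic_limit <- function(b, mu) {
  if (any(mu <= 0)) stop("mu must be > 0")
  if (any(b < 0)) stop("b must be >= 0")
  (1 + b) / mu
}

# deterministic per-run seed derivation in double arithmetic (exact below
# 2^53), reduced below 2^31
.derive_seed <- function(seed, i)
  as.integer((as.numeric(seed) * 1009 + as.numeric(i) * 9176) %% 2147483647)

#' Simulate an inducer dose-response curve
#'
#' Simulates the circuit at each inducer level with \code{replicates}
#' independent seeds and summarises protein mean and noise.  When
#' extrinsic noise is on, each run gets its own freshly generated
#' extrinsic series (seeded from the run seed).
#'
#' @param scheme Circuit scheme (see [build_network()]).
#' @param inducer_grid Strictly increasing vector of free-inducer counts.
#' @param config A [sim_config()]; its seed anchors all per-run seeds.
#' @param rates A [rate_set()].
#' @param extrinsic \code{"off"} or \code{"on"}.
#' @param replicates Independent runs per level (default 3).
#' @param inducer_mode \code{"fast"} or \code{"slow"}.
#' @param species Species summarised (default protein \code{"P"}).
#' @param ou OU parameters used when extrinsic is on.
#' @return A data.frame of class \code{dose_response} with one row per
#'   (inducer, replicate): scheme, inducer, replicate, mean, var, noise.
#'   Use [pool_curve()] for replicate-pooled summaries.
#' @export
dose_response <- function(scheme, inducer_grid, config,
                          rates = rate_set(),
                          extrinsic = c("off", "on"),
                          replicates = 3,
                          inducer_mode = c("fast", "slow"),
                          species = "P",
                          ou = ou_params()) {
  extrinsic <- match.arg(extrinsic)
  inducer_mode <- match.arg(inducer_mode)
  if (length(inducer_grid) == 0) stop("inducer grid must be non-empty")
  if (is.unsorted(inducer_grid, strictly = TRUE))
    stop("inducer levels must be strictly increasing")
  n_pts <- floor(config$duration / config$record_interval) + 1
  out <- vector("list", length(inducer_grid) * replicates)
  k <- 0L
  for (i in seq_along(inducer_grid)) {
    net <- build_network(scheme, rates, inducer = inducer_grid[i],
                         inducer_mode = inducer_mode)
    for (r in seq_len(replicates)) {
      k <- k + 1L
      run_seed <- .derive_seed(config$seed, k)
      cfg <- config
      cfg$seed <- run_seed
      ex <- if (extrinsic == "on") {
        p <- ou
        p$seed <- .derive_seed(run_seed, 1L)
        extrinsic_series(p, n_pts)
      } else NULL
      tr <- simulate_circuit(net, cfg, ex)
      s <- summarize_noise(tr, species = species)
      out[[k]] <- data.frame(scheme = scheme, inducer = inducer_grid[i],
                             replicate = r, mean = s$mean, var = s$var,
                             noise = s$noise)
    }
  }
  res <- do.call(rbind, out)
  attr(res, "extrinsic") <- extrinsic
  attr(res, "inducer_mode") <- inducer_mode
  class(res) <- c("dose_response", "data.frame")
  res
}

#' Pool dose-response replicates
#'
#' Per inducer level: mean of replicate means, mean of replicate noise
#' values (CV^2 averaged across replicates, which is robust to slow
#' extrinsic drift), and the standard error of the noise across
#' replicates.
#'
#' @param curve A [dose_response()] result.
#' @return data.frame: inducer, mean, noise, noise_se, n_rep.
#' @export
pool_curve <- function(curve) {
  sp <- split(curve, curve$inducer)
  out <- do.call(rbind, lapply(sp, function(d) {
    data.frame(inducer = d$inducer[1],
               mean = mean(d$mean),
               noise = mean(d$noise),
               noise_se = stats::sd(d$noise) / sqrt(nrow(d)),
               n_rep = nrow(d))
  }))
  out[order(out$inducer), , drop = FALSE]
}

#' Pick the intermediate-induction grid point
#'
#' Operationalised as the inducer level whose pooled mean expression is
#' nearest half of the fully induced (top-of-grid) mean.
#'
#' @param pooled A [pool_curve()] result.
#' @return The selected inducer level.
#' @export
intermediate_inducer <- function(pooled) {
  full <- pooled$mean[which.max(pooled$inducer)]
  pooled$inducer[which.min(abs(pooled$mean - full / 2))]
}

#' Noise-versus-mean sweep
#'
#' Sweeps one knob and records (mean, noise) pairs for the protein of
#' interest: \code{"kTX1"} varies the transcription rate of an unregulated
#' gene (weakened constitutive expression), \code{"inducer"} varies
#' induction of a regulated scheme, and \code{"kTL_P"} varies the
#' translation rate (ribosome-binding-site strength) at fixed induction
#' grid, returning one curve per translation rate.
#'
#' @param scheme Circuit scheme.
#' @param vary One of \code{"kTX1"}, \code{"inducer"}, \code{"kTL_P"}.
#' @param values Sweep values (rates or inducer counts); for
#'   \code{"kTL_P"} a vector of translation rates combined with
#'   \code{inducer_grid}.
#' @param config A [sim_config()].
#' @param extrinsic \code{"off"} or \code{"on"}.
#' @param replicates Runs per condition.
#' @param inducer_grid Inducer grid used when \code{vary = "kTL_P"}.
#' @param rates Base [rate_set()].
#' @param ... Passed to [dose_response()].
#' @return data.frame with columns (value, inducer, mean, noise, noise_se).
#' @export
noise_vs_mean_sweep <- function(scheme, vary = c("kTX1", "inducer", "kTL_P"),
                                values, config,
                                extrinsic = c("off", "on"),
                                replicates = 3,
                                inducer_grid = NULL,
                                rates = rate_set(), ...) {
  vary <- match.arg(vary)
  extrinsic <- match.arg(extrinsic)
  if (length(values) == 0) stop("sweep values must be non-empty")
  if (vary == "inducer") {
    pooled <- pool_curve(dose_response(scheme, sort(values), config,
                                       rates = rates, extrinsic = extrinsic,
                                       replicates = replicates, ...))
    return(data.frame(value = pooled$inducer, inducer = pooled$inducer,
                      mean = pooled$mean, noise = pooled$noise,
                      noise_se = pooled$noise_se))
  }
  if (vary == "kTX1") {
    out <- lapply(seq_along(values), function(i) {
      r <- rates; r$kTX1 <- values[i]
      pooled <- pool_curve(dose_response(scheme, 1, config, rates = r,
                                         extrinsic = extrinsic,
                                         replicates = replicates, ...))
      data.frame(value = values[i], inducer = NA_real_, mean = pooled$mean,
                 noise = pooled$noise, noise_se = pooled$noise_se)
    })
    return(do.call(rbind, out))
  }
  # kTL_P: one dose-response per translation rate
  if (is.null(inducer_grid)) stop("inducer_grid is required for a kTL_P sweep")
  out <- lapply(seq_along(values), function(i) {
    r <- rates; r$kTL_P <- values[i]
    pooled <- pool_curve(dose_response(scheme, inducer_grid, config,
                                       rates = r, extrinsic = extrinsic,
                                       replicates = replicates, ...))
    data.frame(value = values[i], inducer = pooled$inducer,
               mean = pooled$mean, noise = pooled$noise,
               noise_se = pooled$noise_se)
  })
  do.call(rbind, out)
}

#' Fit a Hill equation to a dose-response curve
#'
#' Least-squares fit of
#' \code{y = y0 + (ymax - y0) * d^n / (K^n + d^n)} by
#' Levenberg-Marquardt, with moment-based starting values.
#'
#' @param dose Dose values (> 0 where used in log-spaced starts).
#' @param response Mean response at each dose.
#' @param normalize If \code{TRUE}, also return data and fitted values
#'   normalised by the fitted value at the maximum dose.
#' @return Object of class \code{hill_fit}: \code{n_h}, \code{K},
#'   \code{y_max}, \code{y_0}, standard errors, and the \code{nls} fit.
#' @export
fit_hill <- function(dose, response, normalize = FALSE) {
  stopifnot(length(dose) == length(response))
  if (length(dose) < 4) stop("need at least 4 points for a Hill fit")
  if (length(unique(dose)) < 2) stop("need at least 2 distinct doses")
  if (diff(range(response)) <= 1e-12 * max(abs(response), 1))
    stop("constant response: Hill coefficient is unidentifiable")
  d <- data.frame(dose = dose, y = response)
  y0_start <- min(response)
  ymax_start <- max(response)
  half <- y0_start + (ymax_start - y0_start) / 2
  K_start <- dose[which.min(abs(response - half))]
  if (K_start <= 0) K_start <- stats::median(dose[dose > 0])
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ y0 + (ymax - y0) * dose^n / (K^n + dose^n),
      data = d,
      start = list(y0 = y0_start, ymax = ymax_start, K = K_start, n = 1),
      lower = c(-Inf, -Inf, 1e-12, 1e-3),
      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) stop("Hill fit did not converge: ",
                             conditionMessage(e)))
  co <- summary(fit)$coefficients
  out <- list(n_h = co["n", "Estimate"], K = co["K", "Estimate"],
              y_max = co["ymax", "Estimate"], y_0 = co["y0", "Estimate"],
              se = co[, "Std. Error"], fit = fit)
  if (normalize) {
    at_max <- stats::predict(fit, newdata = data.frame(dose = max(dose)))
    out$normalized <- data.frame(dose = dose, response = response / at_max,
                                 fitted = stats::fitted(fit) / at_max)
  }
  structure(out, class = "hill_fit")
}

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf("<hill_fit> n_h = %.3g (SE %.2g), K = %.4g, range [%.4g, %.4g]\n",
              x$n_h, x$se[["n"]], x$K, x$y_0, x$y_max))
  invisible(x)
}

#' Fit exponential decay with a half-time
#'
#' Fits \code{v(t) = A * 2^(-t / t_half) + offset}.
#'
#' @param times Time points (minutes).
#' @param values Observed values; must show a decreasing trend.
#' @return Object of class \code{decay_fit}: \code{t_half} (minutes),
#'   \code{amplitude}, \code{offset}, residual sum of squares, \code{nls}
#'   fit.
#' @export
#' @examples
#' t <- seq(0, 300, by = 10)
#' f <- fit_exp_decay(t, 1000 * 2^(-t / 64.1))
#' f$t_half
fit_exp_decay <- function(times, values) {
  stopifnot(length(times) == length(values))
  if (length(times) < 3) stop("need at least 3 points")
  if (stats::sd(values) == 0 || stats::cor(times, values) >= 0)
    stop("values do not show a decreasing trend; decay fit refused")
  d <- data.frame(t = times, v = values)
  off_start <- min(values)
  A_start <- max(values) - off_start
  th_start <- diff(range(times)) / 4
  fit <- tryCatch(
    minpack.lm::nlsLM(v ~ A * 2^(-t / th) + off, data = d,
                      start = list(A = A_start, th = th_start,
                                   off = off_start),
                      lower = c(0, 1e-9, -Inf),
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) stop("decay fit did not converge: ",
                             conditionMessage(e)))
  co <- stats::coef(fit)
  structure(list(t_half = co[["th"]], amplitude = co[["A"]],
                 offset = co[["off"]],
                 rss = sum(stats::residuals(fit)^2), fit = fit),
            class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf("<decay_fit> t_half = %.4g min, amplitude %.4g, offset %.4g\n",
              x$t_half, x$amplitude, x$offset))
  invisible(x)
}
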