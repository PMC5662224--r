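make_cluster <- function(n, fsca, ssch, sdlog = 0.05, seed = 1) {
  set.seed(seed)
  data.frame(FSCA = fsca * exp(rnorm(n, 0, sdlog)),
             SSCH = ssch * exp(rnorm(n, 0, sdlog)),
             FL1A = rnorm(n, 500, 20))
}

test_that("the scatter peak lands on a tight cluster", {
  ev <- make_cluster(5000, 1e4, 1e3)
  pk <- find_scatter_peak(ev)
  expect_lt(abs(log10(pk[["FSCA"]]) - 4), 0.1)
  expect_lt(abs(log10(pk[["SSCH"]]) - 3), 0.1)
})

test_that("with two clusters the peak tracks the larger", {
  ev <- rbind(make_cluster(6000, 1e4, 1e3, seed = 2),
              make_cluster(2000, 1e3, 1e2, seed = 3))
  pk <- find_scatter_peak(ev)
  expect_lt(abs(log10(pk[["FSCA"]]) - 4), 0.15)
  expect_error(find_scatter_peak(data.frame(FSCA = numeric(0),
                                            SSCH = numeric(0))), "empty")
  expect_warning(find_scatter_peak(make_cluster(100, 1e4, 1e3)),
                 "1,000")
})

test_that("gating keeps the peak, excludes the boundary, and is idempotent", {
  g <- gate_spec(1e4, 1e3, 0.25)
  at_peak <- data.frame(FSCA = 1e4, SSCH = 1e3, FL1A = 1)
  expect_identical(nrow(gate_events(at_peak, g)), 1L)
  # squared radius exactly at the threshold: excluded (strict inequality)
  boundary <- data.frame(FSCA = 1e4 * 1.5, SSCH = 1e3, FL1A = 1)
  expect_identical(nrow(gate_events(boundary, g)), 0L)
  just_in <- data.frame(FSCA = 1e4 * 1.4999, SSCH = 1e3, FL1A = 1)
  expect_identical(nrow(gate_events(just_in, g)), 1L)
  ev <- synth_cytometry(cytometry_truth(n_events = 5000, seed = 5))
  g1 <- gate_events(ev, g)
  expect_identical(gate_events(g1, g), g1)
})

test_that("a synthetic cloud built with 1/3 cells gates to about one third", {
  ev <- synth_cytometry(cytometry_truth(n_events = 30000, seed = 8))
  pk <- find_scatter_peak(ev)
  gated <- gate_events(ev, gate_spec(pk[["FSCA"]], pk[["SSCH"]], 0.25))
  frac <- nrow(gated) / nrow(ev)
  expect_lt(abs(frac - 1 / 3), 0.05)
  # the gate isolates intact cells from background-only debris
  expect_gt(mean(gated$is_cell), 0.99)
})

test_that("the convolution fit recovers a shifted log-normal against a point-mass background", {
  sdl <- sqrt(log(1.05))
  ev <- synth_cytometry(cytometry_truth(meanlog = log(500) - sdl^2 / 2,
                                        sdlog = sdl, n_events = 30000,
                                        seed = 9))
  sig <- ev$FL1A[ev$is_cell]
  f <- fit_convolution(sig, 191)
  expect_lt(abs(f$mean / 500 - 1), 0.03)
  expect_lt(abs(exp(f$meanlog) / exp(log(500) - sdl^2 / 2) - 1), 0.03)
  expect_lt(abs(f$sdlog / sdl - 1), 0.1)
})

test_that("the convolution fit recovers parameters against an empirical background", {
  sdl <- sqrt(log(1.05))
  tru <- cytometry_truth(meanlog = log(500) - sdl^2 / 2, sdlog = sdl,
                         background_sd = 30, n_events = 30000, seed = 10)
  ev <- synth_cytometry(tru)
  set.seed(77)
  bg <- rnorm(10000, 191, 30)
  f <- fit_convolution(ev$FL1A[ev$is_cell], bg)
  expect_lt(abs(f$mean / 500 - 1), 0.05)
  expect_lt(abs(f$cv2 / 0.05 - 1), 0.20)
  # moment consistency: mixture mean = background mean + expression mean
  expect_lt(abs(mean(ev$FL1A[ev$is_cell]) - (191 + 500)) / 691, 0.02)
})

test_that("signal indistinguishable from background is flagged non-identifiable", {
  set.seed(3)
  bg <- rnorm(5000, 191, 25)
  sig <- rnorm(5000, 191, 25)
  expect_error(fit_convolution(sig, bg), "non-identifiable")
  expect_error(fit_convolution(numeric(0), bg), "non-empty")
})

test_that("moment estimates agree with the convolution fit at high signal", {
  sdl <- sqrt(log(1.08))
  ev <- synth_cytometry(cytometry_truth(meanlog = log(5000) - sdl^2 / 2,
                                        sdlog = sdl, n_events = 20000,
                                        seed = 12))
  sig <- ev$FL1A[ev$is_cell]
  m <- fit_moments(sig, rep(191, 1000))
  expect_lt(abs(m$mean / 5000 - 1), 0.03)
  expect_lt(abs(m$cv2 / 0.08 - 1), 0.15)
  expect_error(fit_moments(rep(100, 10), rep(191, 10)), "exceed")
})

test_that("bootstrap CIs are deterministic, bracket the fit, and collapse at n_boot = 1", {
  sdl <- sqrt(log(1.05))
  ev <- synth_cytometry(cytometry_truth(meanlog = log(500) - sdl^2 / 2,
                                        sdlog = sdl, n_events = 4000,
                                        seed = 14))
  sig <- ev$FL1A[ev$is_cell]
  b1 <- bootstrap_fit(sig, 191, n_boot = 25, seed = 5, n_bins = 128)
  b2 <- bootstrap_fit(sig, 191, n_boot = 25, seed = 5, n_bins = 128)
  expect_identical(b1$ci, b2$ci)
  expect_lt(b1$ci["mean", 1], b1$fit$mean)
  expect_gt(b1$ci["mean", 2], b1$fit$mean)
  single <- bootstrap_fit(sig, 191, n_boot = 1, seed = 9, n_bins = 128)
  expect_equal(single$ci["mean", 1], single$ci["mean", 2])
})

test_that("simulated molecule counts pass through the cytometry fit", {
  # linear fluorescence scale + constant background on SSA output: the
  # convolution fit recovers the trajectory's mean within 10%
  net <- build_network("bicistronic_autoregulation", inducer = 1e5)
  tr <- simulate_circuit(net, sim_config(duration = 21000, burn_in = 1000,
                                         seed = 33))
  s <- summarize_noise(tr, "P")
  scale_au <- 0.05   # arbitrary fluorescence units per molecule
  sig <- 191 + scale_au * tr$counts[tr$time > 1000, "P"]
  f <- fit_convolution(sig, 191)
  expect_lt(abs((f$mean / scale_au) / s$mean - 1), 0.10)
})

test_that("event tables round-trip through CSV", {
  ev <- synth_cytometry(cytometry_truth(n_events = 200, seed = 4))
  f <- tempfile(fileext = ".csv")
  utils::write.csv(ev[, c("FSCA", "SSCH", "FL1A")], f, row.names = FALSE)
  back <- read_events(f)
  expect_equal(back$FL1A, ev$FL1A)
  f2 <- tempfile(fileext = ".csv")
  utils::write.csv(data.frame(FSCA = 1, SSCH = 2), f2, row.names = FALSE)
  expect_error(read_events(f2), "FL1A")
})
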