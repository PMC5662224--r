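test_that("summarize_noise computes mean, variance and CV^2 on the post-burn-in grid", {
  tr <- structure(list(
    time = 0:100,
    counts = cbind(P = c(rep(0L, 51), rep(100L, 50))),
    extrinsic = rep(1, 101),
    network = build_network("constitutive"),
    config = sim_config(duration = 100, burn_in = 50, seed = 1)),
    class = "trajectory")
  s <- summarize_noise(tr, "P")
  expect_equal(s$mean, 100)
  expect_equal(s$noise, 0)
  expect_identical(s$n, 50L)
  expect_error(summarize_noise(tr, "Q"), "unknown species")
  expect_error(summarize_noise(tr, "P", burn_in = 200), "shorter")
})

test_that("Poisson samples give CV^2 of 1/mean and zero mean errors out", {
  set.seed(31)
  x <- rpois(20000, 25)
  tr <- structure(list(
    time = seq_along(x), counts = cbind(P = x),
    extrinsic = rep(1, length(x)),
    network = build_network("constitutive"),
    config = sim_config(duration = length(x), burn_in = 0, seed = 1)),
    class = "trajectory")
  s <- summarize_noise(tr, "P")
  expect_lt(abs(s$noise / (1 / 25) - 1), 0.1)
  tr$counts[] <- 0L
  expect_error(summarize_noise(tr, "P"), "undefined")
})

test_that("intrinsic limit evaluates (1+b)/mu and guards its domain", {
  expect_equal(intrinsic_limit(0, 100), 0.01)
  expect_equal(intrinsic_limit(1, 2), 1)
  expect_equal(intrinsic_limit(203, 20700), 204 / 20700)
  expect_error(intrinsic_limit(1, 0), "mu")
  expect_error(intrinsic_limit(-1, 10), "b")
})

test_that("an unregulated circuit's dose-response ignores the inducer", {
  cfg <- sim_config(duration = 6000, burn_in = 500, seed = 5)
  p <- pool_curve(dose_response("constitutive", c(10, 1000, 1e5), cfg,
                                replicates = 2))
  expect_lt(diff(range(p$mean)) / mean(p$mean), 0.1)
})

test_that("induced dose-responses increase monotonically within sampling error", {
  cfg <- sim_config(duration = 11000, burn_in = 1000, seed = 19)
  grid <- round(10^seq(1, 5, length.out = 6))
  for (s in c("constitutive_repressor", "bicistronic_autoregulation")) {
    p <- pool_curve(dose_response(s, grid, cfg, replicates = 2))
    expect_true(all(diff(p$mean) > -0.1 * p$mean[-nrow(p)]),
                info = s)
    expect_gt(p$mean[nrow(p)], 2 * p$mean[1])
  }
})

test_that("Hill fits recover generating coefficients on clean curves", {
  for (nh in c(2.24, 0.60, 1.3)) {
    d <- synth_curve_data("hill", list(n_h = nh, K = 20, ymax = 100,
                                       d_min = 0.5, d_max = 2000), n = 14)
    f <- fit_hill(d$x, d$y)
    expect_lt(abs(f$n_h / nh - 1), 0.01)
    expect_lt(abs(f$K / 20 - 1), 0.05)
  }
  # normalization by the fitted top-dose value
  d <- synth_curve_data("hill", list(n_h = 1, K = 20, ymax = 100))
  f <- fit_hill(d$x, d$y, normalize = TRUE)
  expect_equal(f$normalized$fitted[nrow(f$normalized)], 1, tolerance = 1e-6)
})

test_that("Hill fit rejects degenerate inputs", {
  expect_error(fit_hill(1:3, c(1, 2, 3)), "at least 4")
  expect_error(fit_hill(rep(1, 5), 1:5), "distinct")
  expect_error(fit_hill(1:6, rep(2, 6)), "unidentifiable")
})

test_that("exponential-decay fits recover the generating half-time", {
  d <- synth_curve_data("decay", list(t_half = 64.1, A = 1000), n = 25)
  f <- fit_exp_decay(d$x, d$y)
  expect_equal(f$t_half, 64.1, tolerance = 1e-4)
  # with offset and mild noise
  d2 <- synth_curve_data("decay", list(t_half = 120, A = 500, offset = 50,
                                       t_max = 600),
                         noise = 0.02, n = 40, seed = 4)
  f2 <- fit_exp_decay(d2$x, d2$y)
  expect_lt(abs(f2$t_half / 120 - 1), 0.10)
  expect_error(fit_exp_decay(1:10, rep(5, 10)), "decreasing")
  expect_error(fit_exp_decay(1:2, 2:1), "at least 3")
})

test_that("noise_vs_mean_sweep tracks the intrinsic limit for weakened expression", {
  # coarse version of the constitutive-transcription sweep (no extrinsic
  # noise); the full-powered check lives in the acceptance suite
  cfg <- sim_config(duration = 30000, burn_in = 1000, seed = 77)
  ks <- c(1.05e-4, 1.7e-3)
  sw <- noise_vs_mean_sweep("constitutive", "kTX1", ks, cfg,
                            extrinsic = "off", replicates = 2)
  lim <- intrinsic_limit(0.67 / 0.0033, sw$mean)
  expect_true(all(abs(sw$noise / lim - 1) < 0.25))
  expect_error(noise_vs_mean_sweep("constitutive", "kTX1", numeric(0), cfg),
               "non-empty")
  expect_error(noise_vs_mean_sweep("bicistronic_autoregulation", "kTL_P",
                                   0.29, cfg), "inducer_grid")
})

test_that("dose-response curves export as tidy CSV with a manifest", {
  cfg <- sim_config(duration = 1500, burn_in = 500, seed = 2)
  dr <- dose_response("bicistronic_autoregulation", c(100, 10000), cfg,
                      replicates = 2)
  f <- tempfile(fileext = ".csv")
  write_curve(dr, f, manifest = list(seed = 2))
  back <- utils::read.csv(f)
  expect_identical(nrow(back), 4L)
  expect_true(all(c("scheme", "inducer", "replicate", "mean", "var",
                    "noise") %in% names(back)))
  man <- jsonlite::read_json(paste0(f, ".json"), simplifyVector = TRUE)
  expect_identical(man$extrinsic, "off")
  expect_identical(man$seed, 2L)
})
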