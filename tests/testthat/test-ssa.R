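test_that("a silenced gene stays silent", {
  net <- build_network("constitutive", rate_set(kTX1 = 0))
  tr <- simulate_circuit(net, sim_config(duration = 200, burn_in = 10,
                                         seed = 1))
  expect_true(all(tr$counts[, c("M1", "P")] == 0L))
})

test_that("unregulated mRNA matches the birth-death closed form and is Poisson-like", {
  net <- build_network("constitutive")
  tr <- simulate_circuit(net, sim_config(duration = 41000, burn_in = 1000,
                                         seed = 42))
  m1 <- summarize_noise(tr, "M1")
  target <- 10 * 1.7e-3 / 0.0033   # 5.15 transcripts
  expect_lt(abs(m1$mean / target - 1), 0.05)
  # Poisson marginal: CV^2 = 1/mean
  expect_lt(abs(m1$noise * m1$mean - 1), 0.1)
})

test_that("pure-birth event counts follow the analytic Poisson law", {
  # transcription only: M1 at time T counts the events of a Poisson
  # process with rate n_DNA * kTX1
  r <- rate_set(kTL_P = 0, deg_M = 0, deg_P = 0)
  net <- build_network("constitutive", r)
  lambda <- 10 * r$kTX1 * 30 * 60  # 30 simulated minutes
  counts <- vapply(1:200, function(i) {
    tr <- simulate_circuit(net, sim_config(duration = 30, burn_in = 0,
                                           seed = 5000 + i))
    tr$counts[nrow(tr$counts), "M1"]
  }, numeric(1))
  expect_lt(abs(mean(counts) / lambda - 1), 0.1)
  # chi-squared goodness of fit against Poisson(lambda), alpha = 0.01
  breaks <- c(-Inf, 20:41, Inf)
  obs <- table(cut(counts, breaks))
  expctd <- diff(ppois(c(-Inf, 20:41, Inf), lambda)) * length(counts)
  keep <- expctd > 1
  stat <- sum((as.numeric(obs)[keep] - expctd[keep])^2 / expctd[keep])
  pval <- pchisq(stat, df = sum(keep) - 1, lower.tail = FALSE)
  expect_gt(pval, 0.01)
})

test_that("conservation laws hold at every recorded point", {
  net <- build_network("autoregulated_repressor", inducer = 200,
                       inducer_mode = "slow")
  tr <- simulate_circuit(net, sim_config(duration = 5000, burn_in = 100,
                                         seed = 7))
  expect_true(all(tr$counts[, "D1"] + tr$counts[, "D1R"] == 10L))
  expect_true(all(tr$counts[, "D2"] + tr$counts[, "D2R"] == 10L))
  expect_true(all(tr$counts[, "I"] + tr$counts[, "RI"] == 200L))
  expect_true(all(tr$counts >= 0L))
  # fast mode pins the free-inducer count instead
  netf <- build_network("bicistronic_autoregulation", inducer = 200,
                        inducer_mode = "fast")
  trf <- simulate_circuit(netf, sim_config(duration = 2000, burn_in = 100,
                                           seed = 8))
  expect_true(all(trf$counts[, "I"] == 200L))
})

test_that("trajectories are bit-identical under a fixed seed", {
  net <- build_network("bicistronic_autoregulation", inducer = 1000)
  cfg <- sim_config(duration = 2000, burn_in = 100, seed = 123)
  ex <- extrinsic_series(ou_params(seed = 9), 2001)
  a <- simulate_circuit(net, cfg, ex)
  b <- simulate_circuit(net, cfg, ex)
  expect_identical(a$counts, b$counts)
  c2 <- cfg; c2$seed <- 124L
  expect_false(identical(simulate_circuit(net, c2, ex)$counts, a$counts))
})

test_that("a too-short extrinsic series is rejected", {
  net <- build_network("constitutive")
  cfg <- sim_config(duration = 1000, burn_in = 100, seed = 1)
  expect_error(simulate_circuit(net, cfg, rep(1, 50)), "too short")
})

test_that("inducer schedules reset the free pool and reject ambiguous modes", {
  net <- build_network("bicistronic_autoregulation", inducer = 0)
  cfg <- sim_config(duration = 1500, burn_in = 100, seed = 11)
  # degenerate schedule: single step at t = 0 equals plain simulation
  sched <- data.frame(time = 0, inducer = 500)
  a <- simulate_schedule(net, cfg, sched)
  b <- simulate_circuit(build_network("bicistronic_autoregulation",
                                      inducer = 500), cfg)
  expect_identical(a$counts, b$counts)
  # the schedule is visible in the trajectory
  s2 <- data.frame(time = c(0, 700), inducer = c(500, 0))
  tr <- simulate_schedule(net, cfg, s2)
  expect_true(all(tr$counts[tr$time > 700, "I"] == 0L))
  netslow <- build_network("bicistronic_autoregulation", inducer = 10,
                           inducer_mode = "slow")
  expect_error(simulate_schedule(netslow, cfg, sched), "fast inducer mode")
  expect_error(simulate_schedule(net, cfg,
                                 data.frame(time = c(5, 5),
                                            inducer = c(1, 2))),
               "increasing")
})

test_that("inducer wash-out decays protein at the dilution half-time", {
  # equilibrate fully induced, then wash at t = 3000 min; repression is
  # re-established over the first ~hour (the repressor pool must rebuild
  # and bind the DNA), after which the mean decays towards a small
  # residual floor with t_half = ln2 / deg_P = 69.3 min
  net <- build_network("bicistronic_autoregulation", inducer = 0)
  sched <- data.frame(time = c(0, 3000), inducer = c(1e5, 0))
  runs <- lapply(1:5, function(i) {
    cfg <- sim_config(duration = 3800, burn_in = 100, seed = 600 + i)
    simulate_schedule(net, cfg, sched)
  })
  tsel <- runs[[1]]$time >= 3060 & runs[[1]]$time <= 3700
  vbar <- Reduce(`+`, lapply(runs, function(tr)
    tr$counts[tsel, "P"])) / length(runs)
  fit <- fit_exp_decay(runs[[1]]$time[tsel] - 3060, vbar)
  expect_lt(abs(fit$t_half / (log(2) / 1.6667e-4 / 60) - 1), 0.10)
})

test_that("trajectories round-trip through TSV + JSON sidecar", {
  net <- build_network("hybrid", inducer = 100, inducer_mode = "slow")
  cfg <- sim_config(duration = 300, burn_in = 50, seed = 3)
  ex <- extrinsic_series(ou_params(seed = 2), 301)
  tr <- simulate_circuit(net, cfg, ex)
  path <- tempfile(fileext = ".tsv")
  write_trajectory(tr, path)
  back <- read_trajectory(path)
  expect_identical(back$counts, tr$counts)
  expect_equal(back$extrinsic, tr$extrinsic)
  expect_identical(back$network$scheme, tr$network$scheme)
  expect_equal(back$network$rates_vec, tr$network$rates_vec)
  expect_identical(back$config$seed, tr$config$seed)
})
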