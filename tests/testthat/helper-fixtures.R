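# Shared fixtures for the simulation-heavy suites.  Dose-response scans
# are expensive enough that several acceptance properties share one scan
# per scheme; they are computed lazily and cached for the session.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_env))
    assign(name, builder(), envir = .fixture_env)
  get(name, envir = .fixture_env)
}

# default 12-point log-spaced inducer grid spanning 4 decades
default_grid <- function() round(10^seq(1, 5, length.out = 12))

scan_config <- function(seed = 101L) {
  sim_config(duration = 21000, burn_in = 1000, seed = seed)
}

# pooled dose-response scan with extrinsic noise, 3 replicates
scheme_scan <- function(scheme, inducer_mode = "fast") {
  fixture(paste0("scan_", scheme, "_", inducer_mode), function() {
    pool_curve(dose_response(scheme, default_grid(), scan_config(),
                             extrinsic = "on", replicates = 3,
                             inducer_mode = inducer_mode))
  })
}

# higher-power noise estimate at a single inducer level: `reps` seeds of
# 41,000 min (1,000 burn-in) with extrinsic noise
powered_noise <- function(scheme, inducer, reps = 6, seed = 7L,
                          rates = rate_set()) {
  cfg <- sim_config(duration = 41000, burn_in = 1000, seed = seed)
  dr <- dose_response(scheme, inducer, cfg, rates = rates,
                      extrinsic = "on", replicates = reps)
  p <- pool_curve(dr)
  list(noise = p$noise, se = p$noise_se, mean = p$mean)
}

# measured extrinsic plateau: unregulated scheme at default transcription
# rate with extrinsic noise (the "constitutive extrinsic limit")
plateau_fixture <- function() {
  fixture("plateau", function() {
    powered_noise("constitutive", 1, reps = 6, seed = 301L)
  })
}
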