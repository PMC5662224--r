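# circuitnoise

Gene expression from standard inducible systems — a repressor expressed
constitutively, inhibited by an inducer — is noisy: cell-to-cell
variability (noise, the squared coefficient of variation σ²/μ²) sits
well above the ~0.1 "extrinsic noise limit" observed for highly
expressed bacterial genes, and the dose-response is steep.  Expressing
the repressor *bicistronically* with the gene of interest from its own
repressible promoter (negative autoregulation on a shared transcript)
linearizes the dose-response and pushes noise below the extrinsic
limit; a hybrid design that adds a weak constitutive repressor source
recovers most of the dynamic range autoregulation costs.

`circuitnoise` is an R package for systems and synthetic biologists
that implements both halves of the computational analysis behind these
claims:

* **Simulation** — exact Gillespie simulation (Rcpp) of five regulatory
  circuit schemes built as mass-action reaction networks (constitutive;
  constitutive repressor; autoregulated repressor; bicistronic
  autoregulation; hybrid), with extrinsic noise modelled as an
  exponentiated, mean-scaled Ornstein-Uhlenbeck process (τ = 200 min,
  c = 2.5×10⁻⁵ s⁻¹, stationary log-variance cτ/2 = 0.15) multiplying
  all translation propensities.  Analysis operators compute noise
  summaries, inducer dose-responses, noise-versus-mean sweeps, the
  intrinsic limit (1+b)/μ with burst size b = k_TL/deg_M, Hill fits and
  exponential-decay fits.
* **Quantification** — the single-cell measurement pipeline used to
  estimate expression mean and noise from instrument-style data:
  scatter-peak gating of flow-cytometry event tables, maximum-likelihood
  fitting of fluorescence as the convolution of an empirical
  autofluorescence background with a log-normal expression
  distribution, bootstrap confidence intervals, gamma calibration of
  single-molecule spot intensities with linear exposure/power rescaling,
  and size-normalized molecules-per-cell estimates.
* **Synthetic data** — seed-deterministic generators that emulate the
  statistical structure of the cytometry and microscopy inputs, so
  every stage is testable without instrument data.

The numbered scripts under `analysis/` are narrative drivers that
reproduce the main simulation studies and write tidy tables under
`results/`; all computation lives in the package functions.

## Worked example

Simulate the bicistronic autoregulation circuit at saturating inducer
and check the designed repressor level:

```r
library(circuitnoise)

net <- build_network("bicistronic_autoregulation", inducer = 1e6)
tr  <- simulate_circuit(net, sim_config(duration = 21000, burn_in = 1000,
                                        seed = 3))
summarize_noise(tr, c("R", "RI"))   # total repressor pool
#> <noise_summary> R+RI: mean 1020, var 1.078e+04, noise (CV^2) 0.01036, n = 20000
summarize_noise(tr, "P")
#> <noise_summary> P: mean 2.054e+04, var 3.652e+06, noise (CV^2) 0.008655, n = 20000
```

The repressor pool sits at the designed ~1,000 copies per cell
(rate-balance: 10·k_TX1/deg_M · k_TL_R/deg_R ≈ 1.03×10³), and fully
induced protein noise is near the intrinsic limit
(1+b)/μ = 204/20,540 ≈ 0.0099.

Quantification on synthetic flow-cytometry data (30,000 events, true
expression mean 500, noise 0.05, autofluorescence background 191 ± 25):

```r
sdl <- sqrt(log(1.05))
ev  <- synth_cytometry(cytometry_truth(meanlog = log(500) - sdl^2/2,
                                       sdlog = sdl, background_sd = 25,
                                       n_events = 30000, seed = 601))
set.seed(602); bg <- rnorm(10000, 191, 25)
pk    <- find_scatter_peak(ev)
gated <- gate_events(ev, gate_spec(pk[["FSCA"]], pk[["SSCH"]], 0.25))
nrow(gated) / nrow(ev)              # ~1/3 of events pass the scatter gate
#> [1] 0.3313667
boot <- bootstrap_fit(gated$FL1A, bg, n_boot = 100, seed = 603)
boot$fit
#> <convolution_fit> expression mean 500.4, noise (CV^2) 0.05031 (meanlog 6.191, sdlog 0.222)
boot$ci["mean", ]
#>     2.5%    97.5%
#> 498.1404 502.5479
```

The fit recovers the generating mean within 0.1% and the noise within
1%, with a 100-resample bootstrap interval.  Single-molecule
calibration rescales linearly between imaging conditions:

```r
scale_calibration(3669, imaging_condition(17.5, 1.00),
                        imaging_condition(35.0, 0.15))
#> [1] 1100.7
```

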