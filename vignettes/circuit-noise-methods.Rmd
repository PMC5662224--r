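---
title: "Models and methods: stochastic circuit simulation and single-cell quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: stochastic circuit simulation and single-cell quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(circuitnoise)
```

This vignette is the package's own account of the models it implements,
the parameters that matter, the numerical choices made where the design
was genuinely open, and what the synthetic-data tests do and do not show
about real instrument data.

## The regulatory circuits

Five schemes of inducible gene expression are modelled as mass-action
reaction networks over the species D1, D2 (free DNA of the gene of
interest and of a separate repressor gene), their repressor-bound forms
D1:R and D2:R, transcripts M1 and M2, protein of interest P, repressor R,
inducer-bound repressor R:I and free inducer I:

* **constitutive** - unregulated expression (transcription, translation,
  mRNA and protein turnover; 4 reactions);
* **constitutive_repressor** - the common inducible design: the repressor
  is expressed from its own constitutive gene and represses the gene of
  interest (13 reactions);
* **autoregulated_repressor** - the separate repressor gene additionally
  represses itself (15 reactions);
* **bicistronic_autoregulation** - gene of interest and repressor share
  one transcript from one autoregulated promoter (11 reactions);
* **hybrid** - the bicistronic circuit plus a weak, never-repressed
  constitutive promoter that also supplies repressor (14 reactions).

Repression is monomeric: one free repressor binds free DNA and silences
it; no dimerisation or operator cooperativity is modelled.  One inducer
molecule binds a repressor and blocks DNA binding.  DNA-bound repressor
is protected from degradation, and degradation of inducer-bound
repressor liberates its inducer.  The model is solved in unit volume, so
molecule numbers and concentrations coincide and every propensity is in
s^-1.

Default rates (`rate_set()`): transcription 1.7e-3 s^-1 per free DNA
copy (6.7e-4 s^-1 for the hybrid's weak promoter, 40% of the main
promoter; 6.5e-6 s^-1 models strongly weakened constitutive expression),
translation 0.67 s^-1 per transcript for the protein of interest and
0.0333 s^-1 for the repressor, repressor-DNA binding/unbinding
1e-5/1e-4 s^-1, repressor-inducer binding/unbinding 1e-5/1e-7 s^-1, mRNA
turnover 3.3e-3 s^-1 (~5-min lifetime) and protein/repressor removal
1.6667e-4 s^-1 (dilution at a ~69-min doubling time).  Ten unrepressed
DNA copies mimic a medium-copy plasmid.  These choices give a burst size
b = kTL_P/deg_M of about 203 proteins per transcript, a fully induced
mean of about 2.07e4 proteins, and a fully induced repressor pool of
about 1.03e3 - the ~1,000 copies per cell typical of inducible
expression systems.

Inducer exchange with the environment has two limits.  `"fast"` holds
the free-inducer count constant (rapid equilibration across the
membrane); `"slow"` conserves the total pool I + R:I.  The fast limit is
the default; the slow limit reproduces a U-shaped noise-versus-inducer
response (see below).

## Exact simulation with extrinsic noise

`simulate_circuit()` runs the direct Gillespie stochastic simulation
algorithm (Rcpp): exact sampling of the chemical master equation, which
matters because mRNA and DNA copy numbers are single digits.  The
public grid is in minutes; kinetics are computed in seconds.

Extrinsic noise - cell-wide fluctuation of the translation machinery -
is a stationary Ornstein-Uhlenbeck process x(t) with relaxation time tau
= 200 min and diffusion parameter c, exponentiated and scaled by its
empirical mean into a positive, unit-mean factor that multiplies **all
translation propensities** (exactly the reactions flagged
`is_translation`).  The exact discrete OU update is used:
x(t+dt) = x(t) e^(-dt/tau) + N(0, (c tau/2)(1 - e^(-2 dt/tau))),
initialised from the stationary law N(0, c tau/2).

Two numerical choices deserve note:

* **Units of c.**  The defaults quote c = 2.5e-5 without units.  This
  package interprets c in s^-1 (tau converted to seconds), giving
  stationary log-variance c tau/2 = 0.15, factor CV^2 = e^0.15 - 1 ~
  0.16, and - after low-pass filtering through the 100-min protein
  lifetime - a protein-noise plateau of ~0.1, the empirical "extrinsic
  noise limit" of highly expressed bacterial genes.  The per-minute
  interpretation would give variance 2.5e-3 and essentially no extrinsic
  plateau, inconsistent with that behaviour, so s^-1 is the default and
  `ou_params(c_units = "per_minute")` remains available.
* **Piecewise-constant coupling.**  The factor is held constant over
  each 1-min recording interval and propensities are re-drawn at
  interval boundaries (exact within an interval by memorylessness).
  1 min is 0.5% of tau, so the discretisation error is negligible
  relative to Monte-Carlo error.

Burn-in (default 1,000 min of a 101,000-min run; equilibration takes a
few hundred minutes) is simulated with extrinsic noise active and merely
excluded from statistics.  Each simulation consumes one seeded RNG
stream; the extrinsic series carries its own seed, so circuit randomness
and extrinsic realisations vary independently, and a series can be saved
(`write_extrinsic()`) and replayed across schemes for paired
comparisons.

## Noise analysis

`summarize_noise()` reports mean, variance and noise - the squared
coefficient of variation sigma^2/mu^2 - over post-burn-in samples.  For
unregulated expression the intrinsic lower bound is approximately
(1 + b)/mu (`intrinsic_limit()`).  This textbook expression is itself an
approximation: the exact stationary Fano factor of the two-stage model
is 1 + b/(1 + deg_P/deg_M), i.e. about 4.8% below (1+b) at these rates.
Simulated noise therefore sits systematically a few percent below the
(1+b)/mu line; the acceptance checks use a 10% band that accommodates
both the approximation gap and Monte-Carlo error.

`dose_response()` sweeps inducer levels with independent seeds per run;
the default grid is 12 log-spaced counts over four decades (10..1e5; the
response of all regulated schemes transitions near 1e3).  Replicate
noise is summarised by averaging per-replicate CV^2 (robust to slow
extrinsic drift between replicates) with a between-replicate standard
error.  "Intermediate induction" is operationalised as the grid point
whose pooled mean is nearest half the fully induced mean.
`fit_hill()` fits y0 + (ymax - y0) d^n/(K^n + d^n) to mean responses by
Levenberg-Marquardt (uniform weights; the fitted top-dose value is the
optional normaliser), and `fit_exp_decay()` fits A 2^(-t/t_half) +
offset.  The offset matters after an inducer wash: repression at the
rebuilt ~100-copy free-repressor level leaves ~1 of 10 DNA copies
transiently free, a residual floor of order 1-2e3 proteins, and the fit
window should start once repression is re-established (~1 h after the
wash), after which the decay is set by dilution (t_half = ln 2/deg_P =
69.3 min).

Key simulated findings these tools reproduce (all with extrinsic noise
unless noted): the bicistronic circuit's noise dips below the ~0.1
extrinsic plateau at intermediate induction, while the two
separate-repressor schemes show similar noise levels above it at
matched means; every scheme converges on the common plateau at full
induction; the bicistronic dose-response is shallower (smaller Hill
coefficient) than the constitutive-repressor circuit's; the hybrid
trades a modest noise increase at low induction for a roughly threefold
wider dynamic range; and the slow-inducer limit yields a U-shaped noise
response.

The hybrid comparison needs one caveat made explicit.  At low induction
every scheme's mean is small enough that the intrinsic limit alone
(~204/mu) exceeds 0.1, so "noise at or below the extrinsic plateau"
cannot hold - for any circuit - on the lower decades of a four-decade
grid.  The package therefore asserts the plateau comparison over the
autoregulated operating range (grid points with pooled mean at or above
half the fully induced mean) and, below full induction, the pointwise
comparison against the constitutive-repressor circuit, which is the
regime the hybrid is designed for.

## Flow-cytometry quantification

`find_scatter_peak()` locates the mode of the FSCA x SSCH histogram on
64 log-spaced bins per axis.  `gate_events()` keeps events with
((FSCA - peak)/peak)^2 + ((SSCH - peak)/peak)^2 strictly below a
squared-radius threshold (0.25 by default; 0.5625 matches a second
instrument's geometry) - a scale-free ellipse about the mode that
typically passes about one third of events.  The denominator of this
normalised distance is sometimes written ambiguously (peak value versus
event value); normalising by the peak coordinates is adopted here, and
the threshold is explicit in `gate_spec()` so the convention is
switchable.  The boundary is excluded (strict inequality) so gating is
idempotent.

`fit_convolution()` models each gated fluorescence value as an
independent draw from the *empirical* autofluorescence distribution (a
non-fluorescent control sample, binned into 256 cells) plus a draw from
a log-normal expression distribution, and maximises the grouped
(binned-signal) likelihood over (meanlog, log sdlog) by Nelder-Mead from
moment-matched multi-starts (reltol 1e-10).  Binned maximum likelihood
was chosen over per-event likelihood for speed - the bootstrap refits
the model 100 times - at 256 bins the discretisation bias is far below
sampling error at n = 30,000.  The reported expression mean is the mean
of the fitted log-normal; its CV^2 is the scale-invariant noise
estimate.  A signal whose mean does not exceed the background mean by at
least twice its standard error is declared non-identifiable rather than
fitted.  `fit_moments()` provides the direct moment alternative used
when signals are far above background, and `bootstrap_fit()` gives
percentile confidence intervals from 100 resamples of the signal (with
replacement, same size, background fixed).

## Microscopy quantification

`fit_gamma_spots()` fits detected single-molecule spot intensities to a
two-parameter gamma law by maximum likelihood (on unit-mean rescaled
data; the raw scale of ~1e3 counts makes the joint (shape, rate)
optimisation ill-conditioned).  The fitted mean is the counts-per-
molecule calibration; `scale_calibration()` transfers it between imaging
conditions linearly in integration time and laser power (3,669 counts at
17.5 ms/100% becomes 1,100.7 at 35 ms/15% and 110.07 at 35 ms/1.5%).
`estimate_molecules()` divides integrated, background-subtracted cell
fluorescence by the calibration, and `size_normalize()` divides by cell
area and multiplies by the mean area.  Note the normalisation preserves
the mean only approximately: for area-independent expression the ratio
of means is E[a]E[1/a] = e^(sdlog^2), about +1% at the realistic area
spread sdlog ~ 0.1.  Upstream image processing (spot detection,
flat-fielding, segmentation) is out of scope; the module consumes the
intensity lists and per-cell tables such pipelines emit.

## Synthetic data: what it does and does not show

`synth_cytometry()` generates event tables exactly from the model the
fit assumes: a tight log-normal scatter cloud at the peak for intact
cells (one third of events by default), debris with weak scatter far
outside the gate carrying background-only fluorescence, and cell
fluorescence = background draw + log-normal draw, with the background a
point mass at 191 counts by default (optionally widened).
`synth_microscopy()` draws gamma spots, unit-mean log-normal cell areas,
log-normal expression scaled by relative area, and calibrated cell
intensities.  `synth_curve_data()` produces Hill and exponential-decay
fixtures (deterministic at zero noise).

Passing recovery tests on these generators demonstrates estimator
correctness - the fit recovers the parameters of the model it assumes,
at realistic sample sizes (30,000 events; 858 spots; 300 cells) and
realistic parameter values.  It does not demonstrate robustness to real
instrument pathologies: non-log-normal expression tails, fluorescence
compensation, doublets inside the gate, detector saturation, or
photobleaching.  Those effects are deliberately outside the generative
model, and conclusions about real data require the usual instrument
controls.

## Problem sizes and reproducibility

Full-length runs (101,000 min) are supported but statistically
unnecessary for the package's checks.  The test and acceptance suites
use 21,000-min scans (1,000-min burn-in) with 3 seeds for dose-response
shapes, 41,000-min runs with 6 seeds where two schemes' noise values are
compared pointwise (extrinsic noise decorrelates over ~2 tau = 400 min,
so these give ~600 effective samples and ~6% relative error on CV^2),
and transcription-sweep durations scaled so every condition accumulates
at least ~1,000 transcription bursts per seed.  OU generator statistics
are averaged over 100 independent series of 1e5 samples, because a
single series of that length carries ~9% Monte-Carlo error on its
variance - too coarse to check a 5% band.  Every stochastic component
(simulation, extrinsic series, generators, bootstrap) is a pure function
of its seed; `scripts/acceptance.R` derives all of its seeds from one
`--seed` argument.

## Known limitations

* Cell division is modelled as first-order dilution; no binomial
  partitioning at division, no cell-cycle gene-dosage effects, and no
  plasmid copy-number variation (the 10 DNA copies are fixed).
* The repressor binds as a monomer to a single operator per promoter;
  real tet-family promoters with two operators and dimeric/tetrameric
  repressors are steeper and can be bimodal at intermediate induction -
  observed experimentally but outside this model.
* Extrinsic noise enters translation only; transcription-side or
  degradation-side extrinsic fluctuations are not modelled.
* The direct SSA with full propensity recomputation is ample for these
  network sizes (<= 16 reactions) but is not tuned for large networks.
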