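---
title: "Estimating single-cell transcription rates from reporter time courses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating single-cell transcription rates from reporter time courses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ratescope)
```

## The problem

Transiently transfecting cells with a fluorescent reporter and imaging them
over two days yields, for each cell, a fluorescence onset curve.  The
quantity of biological interest — the per-copy transcription rate driven by
the promoter or cis-regulatory module (CRM) on the plasmid — is confounded
by the number of plasmid copies the cell happened to take up: in the
observable law, copy number `c` and transcription rate `tau` appear **only
as the product `c * tau`**.  No amount of data from one cell can separate
them.

`ratescope` implements the hierarchical solution: per-cell parameters are
draws from population distributions whose hyperparameters are estimated
jointly with all cells of all constructs, and a *single* copy-number
population distribution is shared by every construct.  Rates are then
estimated relative to that one copy-number distribution, which makes them
comparable across constructs even though their absolute scale remains
arbitrary (we anchor the copy-number median at 1).

## The single-cell layer

For each cell, mRNA `M(t)` and protein `P(t)` follow a chemical Langevin
(diffusion) approximation of the reporter kinetics,

$$dM = (c\,\tau(t) - \delta_M M)\,dt + \sqrt{c\,\tau(t) + \delta_M M}\;dW_1,$$
$$dP = (\alpha M - \delta_P P)\,dt + \sqrt{\alpha M + \delta_P P}\;dW_2,$$

with observations \(F(t_i) = \kappa P(t_i) + \varepsilon_i\),
\(\varepsilon_i \sim N(0, \sigma^2)\).  The transcription rate follows a
telegraph-with-switch form: \(\tau(t) = \tau_0\) (basal) for \(t < T\) and
\(\tau_1\) (active) for \(t \ge T\); `T` is the switch time.  The diffusion
terms are the square roots of summed production and degradation
propensities, the standard chemical-Langevin convention, with independent
Wiener processes per species.  The CLE is a large-copy-number
approximation, so simulated paths are reflected at zero to absorb the rare
undershoots.

Kinetic constants are configuration, not estimated: defaults are
`delta_M = 0.01`/min (mRNA half-life about 70 min), `delta_P = 5e-4`/min
(a stable Venus-class protein), `alpha = 1`/min per mRNA and `kappa = 1`
AU/molecule.  They set the unit system of the reported rates.

## Likelihood

`trace_loglik()` uses a continuous-discrete Gaussian filter: between
observations, the state mean follows the drift ODE (RK4, substeps split at
the switch time) and the state covariance accumulates the CLE diffusion
evaluated along the predicted mean; at each observation the Gaussian
update is applied.  The linear drift makes this fast and accurate; the
filter substep defaults to 2 min, comfortably below the slowest time
constants of the kinetics (1/delta_M = 100 min) and the 30-min imaging
cadence.  A useful structural property, used heavily in the tests: the
filter inherits the exact `(c, tau) -> (gamma c, tau/gamma)` invariance of
the model, to floating-point accuracy.

## The population layer and the sampler

Each latent quantity (`c`, `tau0`, `tau1`, `M0`, `P0`) has a log-normal
population distribution with parameters `(a, b)`; rate layers are
per-construct, the copy-number layer is global with `a` fixed at 0 (the
scale anchor), and initial-condition layers are global.  The switch time
gets a flat prior over the observation window — we found no reason to
impose a population shape on activation timing, and the generator can
still draw `T` from any window.

`fit_rates()` runs Metropolis-within-Gibbs: per sweep, each cell's
parameters are updated by log-scale random walks (windowed, reflected walk
for `T`; `tau0 <= tau1` enforced by rejection), hyperparameters are redrawn
conjugately (normal-inverse-gamma on the log scale), and the global
measurement variance `sigma2` takes a Metropolis step on its log against
the summed likelihood (the filter marginalises the latent states, so no
exact conjugate update exists for it).

Two sampler details matter in practice:

* **Ridge moves.** Because only `c * tau` is likelihood-identified, single
  parameter updates crawl along the identifiability ridge.  The sampler
  therefore includes a joint proposal `(c, tau0, tau1) -> (gamma c,
  tau0/gamma, tau1/gamma)`.  The likelihood is exactly invariant, so the
  move costs no filter evaluation and is accepted on the population-prior
  ratio alone.  Without it, potential-scale-reduction factors of 2-5 are
  common; with it, chains at the scales used in the tests reach
  split-Rhat below 1.01.
* **Variance apportionment is a modelling commitment.**  The data constrain
  only the *total* log-variance of the product `c * tau`, never its split
  between the copy-number and rate layers.  The split is decided by the
  inverse-gamma variance hyperpriors.  The default (`rate_var_prior =
  c(3, 0.06)`, `copy_var_prior = c(2, 0.5)`) treats the per-copy rate as
  chiefly a property of the construct and assigns cell-to-cell expression
  variability to plasmid copy number — the same stance the hierarchical
  method takes when it explains divergent trajectories of two cells of one
  experiment by copy number rather than rate.  Users who believe rates
  vary strongly between cells of one construct should widen
  `rate_var_prior`, with the understanding that per-cell posterior mean
  copy numbers and rates will then co-vary positively across cells: both
  inherit the identified product, so decorrelation of the two estimates is
  a direct consequence of the rate-homogeneity prior, not an independent
  discovery of the sampler.

Initialization is method-of-moments: the late-time slope of an onset curve
approximates `kappa * alpha * c * tau1 / delta_M`, giving a starting
active rate (with `c = 1`); the switch time starts at the 20%-range
crossing.  Non-first chains are jittered for overdispersed starts.
Proposal steps adapt toward 30% acceptance during burn-in only.  The
publication-scale default is 2 chains of 50,000 sweeps (20,000 burn-in,
thinning 10); the package's own tests use 20,000-sweep chains on
two-construct studies, which complete in minutes and reach the diagnostics
thresholds above.

## What the synthetic-data generator emulates — and what it does not

`simulate_study()` reproduces the study design the package targets:
19 constructs, 30-35 cells each, images every 30 min for 48 h, one shared
log-normal copy-number distribution (default sdlog 0.6, median 1:
transfected cells receive widely varying plasmid loads), per-construct
log-normal active rates with population means spread over 2-14 AU (the
span of published population tables) and sdlog 0.7, basal rate a uniform
0-20% fraction of the active rate, switch times uniform over the window,
and Gaussian measurement noise (default sd 200 AU against signals that
cross the 8,000 AU preselection threshold).  Ground truth is always
emitted alongside the traces, because parameter recovery is the package's
acceptance surface.

It deliberately does **not** model: transcriptional bursting beyond the
single basal-to-active switch, fluorophore maturation, cell growth and
size, image formation or segmentation artefacts.  Passing recovery tests
on this generator therefore shows that the inference machinery is correct
*for the model class*; it cannot show that the model class captures every
feature of real imaging data.  Optional division events (signal halving at
a configurable time plus a marker) exist only to exercise the
preprocessing rules.

A note on the recovery tests' design: the identified construct-level rate
ratio differs from the generating population ratio by the realized
construct-mean copy-number draw, with log-scale standard deviation
`sqrt((b_c^2 + b_1^2) * 2 / n_cells)`.  The two-construct recovery
studies in the tests use copy sdlog 0.3 and rate sdlog 0.25 with 20 cells
per construct so that this irreducible design noise (about 0.12 log units)
stays well inside the recovery band being asserted; this is a power
calculation for the test, not a claim about real transfections.

## Preprocessing rules

`preprocess_traces()` applies, in order: preselection (keep a trace iff at
least 10 samples lie strictly above 8,000 AU — untransfected
autofluorescence tops out near 7,000 AU), in-silico division
synchronization (split at each marker, the boundary sample opening the new
generation, since the post-mitotic signal drop marks the daughter),
truncation at the first global fluorescence maximum (the reporter dilutes
into daughters after division, so the rising phase is the single-cycle
portion; first occurrence on ties), a minimum-length filter, and seeded
random subsampling of 30-35 curves per construct.  "Above" is strict;
the threshold applies to stored fluorescence values as given.  All
dispositions are recorded in a QC report with the seed.

## Downstream statistics

`summarize_cells()` reports per-cell posterior mean, SD, CV (= SD/mean)
and SNR (= 1/CV) of the active rate, switch-time medians and centered 90%
widths, and a bimodality flag (two- vs one-component Gaussian mixture, BIC
margin 10).  Because the figures in this literature describe the active
rate spectrum, `tau1` summaries are the default; `tau0` and the
window-averaged rate `(tau0 T + tau1 (t_end - T)) / t_end` are available
where the distinction matters.  `build_rate_stack()` produces the sorted
per-cell density heat map (Silverman bandwidth on log-rate samples,
log-spaced grid, trapezoid-normalized columns).  `population_stats()` and
`fold_change()` give the construct-level tables and ratios;
`lognormality_ks()` tests log-normality of single-cell means with a
parametric-bootstrap (Lilliefors-style) p-value, since estimating the
normal parameters inflates the naive KS p (the naive value is reported
alongside for comparability); `cv_mean_trend()`, `fit_sd_gamma()`,
`containment_fraction()` and `classify_behavior()` cover the noise-mean
relationship, gamma fits to per-cell rate SDs, the CRM "filter"
(containment) metric with quantile rank-matching of central 90% intervals,
and the four-class behavior taxonomy (mixture evidence, then cohort
upper-quartile CV, then mean relative to the cohort median — the class
names come from the field; the thresholds are this package's explicit
conventions, since no formal rule exists).

## Numerical choices and degenerate inputs

* Euler-Maruyama substep 0.1 min (drift via RK4, so the noise-free path
  matches the ODE oracle to better than 1e-6 relative); filter substep
  2 min; both configurable.
* Substeps never straddle the switch-time discontinuity.
* `sigma2 = 0` with data off the deterministic path yields `-Inf`
  log-likelihood, documented and tested.
* Zero-variance posteriors flag SNR as undefined rather than dividing by
  zero; constant chains are flagged "degenerate" by the diagnostics.
* KS null tables are memoised per sample size under an isolated RNG state,
  so calibrated p-values are reproducible and cheap in simulation loops.
* Time is stored in minutes on the grid; fluorescence in AU.

## Known limitations

Absolute rates and copy numbers are not estimable, only ratios against the
anchored copy-number distribution; the variance split between copy number
and rate is prior-driven (see above); the Gaussian filter is an
approximation to the CLE density, accurate in the many-molecule regime the
CLE itself assumes; and single-switch telegraph dynamics cannot represent
repeated bursting, which stable reporters cannot resolve anyway.

## A small worked run

```{r, eval = FALSE}
des <- default_study_design(n_constructs = 2, seed = 42)
des$cells <- c(20L, 20L)
study <- simulate_study(des)
pp <- preprocess_traces(study$traces, seed = 1)
fit <- fit_rates(pp$traces,
                 constants = kinetic_constants(sigma2 = 4e4),
                 control = mcmc_control(iterations = 6000, burnin = 2000,
                                        thin = 5),
                 seed = 1)
summary(fit)
plot(fit, type = "stack")
```
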