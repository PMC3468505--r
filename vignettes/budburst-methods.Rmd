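---
title: "Process-based budburst modelling with budburst"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Process-based budburst modelling with budburst}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(budburst)
```

## The modelling problem

Spring budburst of temperate deciduous trees is driven by two accumulated
temperature signals: *chilling* (cold exposure that releases winter
dormancy) and *forcing* (warm exposure that drives bud development once
dormancy is released).  Warming acts on the two in opposite directions — it
speeds forcing but can starve chilling — so the response of budburst dates
to climate warming is potentially non-linear, and the choice between
one-phase (forcing-only) and two-phase (chilling + forcing) models matters
most in warm scenarios.

`budburst` implements the five classical daily-rate models in a common
framework.  On each day $d$, a chilling rate $R_c(T_d)$ and a forcing rate
$R_f(T_d)$ are computed from the daily mean air temperature $T_d$ and
accumulated into states $S_c = \sum R_c$ (chilling units, CU) and
$S_f = \sum R_f$ (forcing units, FU).  Budburst is the first day on which
$S_f$ reaches a forcing requirement $F^*$:

* **TTM** (Thermal Time): $R_f = \max(0, T - T_b)$ accumulated from a start
  day $t_{1f}$; no chilling.  3 parameters.
* **SM** (Sequential): triangular $R_c$ (zero outside
  $(T_{min}, T_{max})$, peak 1 at $T_{opt}$); sigmoid
  $R_f = c / (1 + e^{-a (T - b)})$ begins only when $S_c \ge C^*$.
  8 parameters.
* **PM** (Parallel): chilling and forcing run in parallel from 1 September;
  $R_f$ is scaled by the competence
  $K_f = K_m + (1 - K_m)\min(S_c / C^*, 1)$.  9 parameters.
* **AM** (Alternating): chill days ($T < T_c$, strictly) counted from
  1 November; linear forcing from 1 January; budburst when
  $S_f \ge a + b\, e^{c S_c}$ with the requirement re-evaluated daily
  against the running $S_c$.  8 parameters.
* **UM** (Unified): one sigmoid family for both rates,
  $R_c = 1/(1 + e^{C_a (T - C_c)^2 + C_b (T - C_c)})$ from 1 September and
  $R_f = 1/(1 + e^{-F_b (T - F_c)})$ once $S_c \ge C^*$, with
  $F^* = w\, e^{k S_c(t_{2c})}$.  9 parameters.

Because the forcing sigmoids are written with a leading minus and positive
slope parameters, "increasing in temperature" holds by construction; this
is a reparameterisation of forms in the source literature that use negative
slope parameters.  Day-valued anchors follow a fixed axis with index 1 =
1 September of the pre-budburst year and a 365-day year
(`day_anchors()`): 1 November = 62, 1 December = 92, 1 January = 123,
22 February = 175, 30 June = 303 (the prediction horizon).  A prediction
that never reaches $F^*$ before the horizon is `NONE`, a first-class
outcome rather than an error.

Three conventions are pinned by worked examples in the test suite: the
first forcing day contributes its full rate (constant $T = T_b + 1$ with
$F^* = 10$ gives budburst on the 10th forcing day); forcing begins on the
same day $S_c$ first reaches $C^*$ (trigger without lag); and the AM chill
day uses a strict inequality ($T = T_c$ accumulates nothing).  Two further
interpretation choices deserve note: the Alternating model's day anchors
$t_{1f}, t_{1c}$ are fixed at 1 January / 1 November (they are listed among
the model's eight parameters but are not calibrated, and $t_{2c}$ is unused
by the day loop because the requirement tracks the *running* $S_c$); and
the Parallel model uses triangular chilling with competence-scaled sigmoid
forcing — the two equations its description cross-references — treating the
chilling/forcing equation-number swap in the source description as a typo.

## Prediction engines

`predict_budburst()` has two engines.  The `"fast"` engine vectorises the
rate computations and accumulates with an explicit left-to-right
double-precision sum; the `"reference"` engine is a plain day-by-day loop.
Because both perform the same additions in the same order and precision,
they agree *exactly* (the tests assert identity on hundreds of random
parameter draws).  The fast engine deliberately avoids `base::cumsum`,
whose extended-precision accumulator would differ from the loop in the last
bits.

```{r predict-example}
s <- synthesize_daily_temperature(climate_config(seed = 1), 303)
predict_budburst("SM", default_design()$species$beech$params, s)
```

## Calibration

Calibration is Bayesian: a Metropolis–Hastings random walk under flat
priors on a finite box, with a Gaussian residual likelihood on observed
budburst day indices.  Choices the source methodology leaves open are fixed
as follows and shipped as defaults:

* **Priors.** Each parameter has a documented finite box
  (`default_parameter_bounds()`); boxes are wide and sign-constrained
  (e.g. $T_b \in [-5, 15]$ °C, $F^* \in (0, 500]$ FU,
  $C^* \in (0, 200]$ CU, $t_{1f} \in$ [1 Nov, 22 Mar]).  Structural
  orderings ($T_{min} < T_{opt} < T_{max}$) are part of the prior support.
* **Residual model.** Gaussian with standard deviation $\sigma$ (days),
  calibrated as a nuisance parameter with flat prior on $(0.1, 20]$ days;
  a fixed $\sigma$ is available via `mcmc_config(sigma = ...)`.  A `NONE`
  prediction gives $-\infty$ log-likelihood, so such proposals are
  rejected.
* **Kernel.** Independent Gaussian steps per parameter, initial scale 5 %
  of the prior range, adapted toward 20–50 % acceptance during burn-in
  only, so the retained chain uses a fixed, valid kernel.  The start point
  is the best of the box midpoint and 200 scored uniform draws, which keeps
  the chain out of flat $-\infty$ regions (important when chilling-failure
  regions make the likelihood surface disconnected in practice).
* **Day-valued parameters** ($t_{1f}$, $t_{2c}$) are proposed continuously
  and rounded at evaluation time, keeping the walk on a connected support.
* **Chain length.** `mcmc_config()` defaults to 50,000 iterations with
  10,000 burn-in.  The shipped analyses (pipeline default, acceptance
  script, tests) use 5,000–12,000 iterations, sized so that the
  maximum-likelihood fit and prediction-level summaries are stable for
  these 3–9 parameter problems; posterior spread summaries would warrant
  the longer default.
* **Reported fit.** `best_fit()` returns the maximum-likelihood retained
  sample (ties broken by earliest iteration), the analogue of a best-fit
  parameter table.

The sampler itself is exposed as `mh_sample()` and is checked against an
analytic Gaussian posterior; calibration is checked by a
prediction-recovery experiment (TTM-generated observations, $\sigma = 1$
day, recovery RMSE $\le 2$ days).  Parameter values themselves can be
weakly identified — several parameter combinations yield nearly identical
predictions — so recovery is asserted at the prediction level, not
parameter-by-parameter.

## Evaluation

Goodness of fit uses RMSE (days), Nash–Sutcliffe model efficiency
$ME = 1 - RSS/TSS$, Pearson's $r$, and AIC in the residual-sum-of-squares
form $t \ln(RSS/t) + 2(p + 1)$ with $p$ the nominal model parameter count
(the $+1$ counts the residual variance); no small-sample correction is
applied.  AIC is reported only for whole-dataset (internal) fits.  A
numerically perfect fit has no defined AIC under this form and is reported
as `NA` with an `undefined-perfect-fit` flag.  *Internal* validation
calibrates and scores on the full dataset; *external* validation
calibrates on a random half, stratified by species × treatment so every
treatment appears in both halves, and scores on the other half.  When a
fitted model predicts `NONE` for a scored observation, the prediction is
replaced by the horizon day (index 303) and flagged — scoring stays total
while chilling-failure misfits are penalised heavily.

The temperature-sensitivity analysis regresses each treatment's mean
budburst advancement (treatment mean − control mean, days) on the mean
warming it experienced from 1 December to its mean budburst day
(`observed_warming_deltas()`), unweighted through treatment means; the
slope is in days per °C, negative meaning warming advances budburst.

## The synthetic experiment

No sapling-level observations are distributed with the package, so all
analyses run on a synthetic generator that emulates the structure of a
factorial winter/spring warming chamber experiment:

* a Belgian-normal climate — annual mean 9.6 °C, annual cosine with monthly
  means from 2.2 °C (January) to 17.0 °C (July), coldest day 15 January —
  plus AR(1) noise (coefficient 0.7, marginal sd 3 °C, typical mid-latitude
  day-to-day persistence);
* seven treatments: the 2×2 factorial W0S0/W6S0/W0S6/W6S6 (winter warming
  1 December–22 February, spring warming from the 22 February transfer
  day, which counts as spring) plus auxiliary W2S0/W2S2/W2S6;
* 4 chambers × 3 saplings per treatment and species (12 per treatment, 48
  over the main factorial, 84 over all seven); each chamber draws a
  realized temperature offset (sd 0.3 °C, the chambers held warming within
  a few percent of nominal); each sapling adds rounded Gaussian jitter
  (sd 2 days);
* observation censoring to a phenology visit grid (every 2 days by
  default, anchored at 1 February); recorded dates are never earlier than
  the true day and at most one interval later.

The default species are generated from the Sequential model with chilling
requirements 120 (beech) > 100 (oak) > 50 (birch) chill-day-equivalents.
The chilling triangles are wide enough that every treatment meets its
requirement — the design is forcing-dominated, matching the experimental
finding that chilling occurred even in warmed chambers — but narrow enough
that winter warming slows chilling and delays the forcing trigger by a few
weeks, which is what keeps winter-warmed saplings from flushing in
mid-winter.  Forcing requirements are tuned so the generated per-species
budburst ranges fall inside the reported observation windows (birch DOY
60–95, oak 78–125, beech 95–140, within ±15 days) and control budburst
lands in mid April (birch), early May (oak) and mid May (beech).  Under
this design all warmed treatments advance budburst and spring warming
advances more per experienced °C than winter warming.

`beech_stress_design()` is the chilling-limited counterpart: a narrow
triangle (feet −5/16 °C) and a high requirement ($C^* = 95$) make the
continuously warmed W6S6 treatment satisfy chilling only in late spring, so
its budburst is far later than any forcing-only account allows.  Because
W6S6 and W0S6 share identical post-transfer temperatures, a Thermal Time
model cannot separate them, while the Sequential model can — this is the
mechanism by which the two-phase model wins the comparison on
chilling-limited data, and it is asserted over ten replicate seeds (SM
beats TTM on whole-dataset RMSE and AIC in at least 7 of 10).

What the generator does *not* emulate: photoperiod constraints, bud-stage
progression (only the single budburst date is produced), provenance or
within-species genetic variation, sub-daily temperature structure, and
soil-moisture effects.  Passing tests therefore demonstrate correctness of
the implementation and internal consistency of the analysis chain on data
with this structure — not transferability of any fitted parameter values to
field observations.

## Numerical choices and degenerate inputs

* Sigmoid exponents are clamped to ±700 before `exp()` to avoid overflow.
* With integer daily sampling the synthetic annual cosine never hits its
  crest exactly, so the July extreme is 17.0 °C to ~3×10⁻⁴ rather than
  exactly.
* Temperature CSVs are written with 17 significant digits so read–write
  round-trips are bit-exact; gaps, duplicates and unparseable rows are
  rejected with the offending day or line.
* A stratum with a single sapling goes to the training half of an external
  split with a warning.
* In the generator, a species that cannot flush in the *control* treatment
  is a design error; in warmed treatments a missing budburst is recorded
  at the horizon and flagged `censored_at_horizon`, so extreme scenarios
  remain analysable.
* All randomness is derived from user-visible seeds; chains, splits and
  generated datasets are bit-reproducible, and repeated pipeline runs
  write byte-identical reports.

## Problem sizes

The shipped test-suite and acceptance analyses use the full experimental
replication (84 observations per species across 7 treatments; 48 in the
stress scenario) with 5,000-iteration (TTM) and 12,000-iteration (SM)
chains, and 10 replicate seeds for the model-selection experiment.  These
sizes were chosen as the smallest at which the reported summaries are
stable; they can be raised freely via `mcmc_config()`.

## Limitations

Beyond the generator's scope notes above: AIC comparisons use the nominal
parameter counts (including the Alternating model's fixed day anchors, to
match the published counts) rather than effective parameter counts;
convergence diagnostics beyond the acceptance rate are delegated to
external tools via the exported chain CSVs; and the calibration treats
chambers as exchangeable within treatments (chamber offsets are noise, not
modelled effects).
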