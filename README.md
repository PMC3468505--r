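# budburst

Process-based modelling of spring budburst dates of temperate deciduous
trees from daily mean air temperature, with Bayesian calibration and model
comparison.

Budburst timing is controlled by two accumulated temperature signals:
**chilling** (winter cold that releases bud dormancy) and **forcing**
(spring warmth that drives bud development afterwards).  Climate warming
speeds forcing but can starve chilling, so warming does not necessarily
advance budburst — for species with large chilling requirements it can even
delay it.  Separating the two effects, and deciding whether a forcing-only
model is enough, requires process models fitted to experiments in which
winter and spring warming are manipulated independently.

The package is aimed at phenology modellers and ecophysiologists.  It
provides:

* the five classical temperature-driven budburst models as daily rate
  functions, state accumulators and threshold rules with a uniform
  `predict_budburst()` interface — Thermal Time (TTM), Sequential (SM),
  Parallel (PM), Alternating (AM) and Unified (UM).  On each day,
  rates R_c(T) and R_f(T) accumulate into states S_c and S_f, and budburst
  is the first day with S_f ≥ F\*; in the two-phase models forcing starts
  once S_c ≥ C\* (SM, UM), competence scales forcing (PM), or F\* decreases
  with accumulated chilling (AM, UM);
* Metropolis–Hastings random-walk calibration under flat priors with a
  Gaussian residual likelihood (`metropolis_hastings()`, `best_fit()`,
  generic sampler `mh_sample()`);
* model comparison by RMSE, Nash–Sutcliffe model efficiency
  ME = 1 − RSS/TSS, and AIC = t·ln(RSS/t) + 2(p+1), with internal
  (fit = score set) and external (random stratified half) validation
  (`cross_validate()`, `run_model_comparison()`);
* a temperature-sensitivity analysis regressing budburst advancement on
  the mean warming experienced from 1 December to budburst
  (`sensitivity_slope()`);
* a synthetic-data generator emulating a factorial winter/spring warming
  chamber experiment on beech, oak and birch saplings — seven treatments
  (W0S0…W6S6, transfer on 22 February), 4 chambers × 3 saplings per
  treatment, chamber- and sapling-level noise, visit-grid censoring
  (`default_design()`, `beech_stress_design()`,
  `generate_observations()`).

All series live on a fixed day axis: index 1 = 1 September of the
pre-budburst year, 365-day year, DOY = index − 122 (`day_anchors()`).

## Worked example

Generate the synthetic warming experiment, fit the Thermal Time model to
beech by MCMC with internal validation, and measure warming sensitivity:

```r
library(budburst)

obs    <- generate_observations(default_design(seed = 1))
series <- treatment_series(synthesize_daily_temperature(climate_config(), 303),
                           standard_treatments())
beech  <- obs[obs$species == "beech", ]

cv <- cross_validate("TTM", beech, series, mode = "internal",
                     config = mcmc_config(n_iterations = 20000,
                                          burn_in = 6000, seed = 42))
cv$metrics
#>   model     mode  n     rmse        me      aic pearson_r n_none
#> 1   TTM internal 84 3.366502 0.9546497 211.9309 0.9827291      0

deltas <- observed_warming_deltas(obs, series)
round(deltas, 2)
#> W0S0 W6S0 W0S6 W6S6 W2S0 W2S2 W2S6
#> 0.00 3.95 1.78 6.00 1.17 2.00 3.06

sensitivity_slope(obs, deltas)
#> <sensitivity_result> slopes (days per degC):
#>  species     slope
#>    beech -6.278226
#>      oak -6.187849
#>    birch -5.758150
```

Reading the output: the fitted TTM reproduces the 84 beech budburst dates
to 3.4 days RMSE with model efficiency 0.95 (1 = perfect, 0 = no better
than the mean date).  The warming deltas show why the treatments differ:
winter-only warming (W6S0) raises the December-to-budburst mean temperature
by more than spring-only warming (W0S6, a shorter window), yet spring
warming advances budburst more — the regression slopes say budburst comes
5.8–6.3 days earlier per °C of experienced warming.  On chilling-limited
data (`beech_stress_design()`), where continuous warming delays dormancy
release, the Sequential model clearly beats the Thermal Time model
(whole-dataset RMSE 3.2 vs 6.1 days, AIC 128 vs 181 in the shipped
acceptance run) because W6S6 and W0S6 share identical spring temperatures
and only a chilling mechanism can separate them.

A thin command-line front end over the same functions is included at
`inst/cli/budburst.R` (subcommands `simulate`, `fit`, `compare`,
`sensitivity`).

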