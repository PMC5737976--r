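# caritrend

Trend detection and power analysis for coastal monitoring time series.

Long-term monitoring networks such as CARICOMP (the Caribbean Coastal
Marine Productivity program) collect weekly water temperature, salinity,
and visibility (Secchi distance) at fixed reef, seagrass, and mangrove
stations. Deciding whether a station has warmed or lost water clarity —
and which local conditions explain where clarity is being lost — is a
serial-correlation problem: monthly means remember their past, and
ordinary regression wildly overstates trend significance. `caritrend`
packages the full analysis for scientists running or reanalysing such
networks.

## What it does

* **Data handling** — parses the weekly delimited-text database, averages
  to calendar-month means, and keeps only series with ≥ 3 years of span
  and ≥ 30 monthly records.
* **Trend model** — fits, per station and variable,

  y_t = μ + (ω/12)·t + Σ_j [β₁ⱼ sin(2πjt/12) + β₂ⱼ cos(2πjt/12)] + N_t,
  N_t = φ·N_{t−1} + ε_t,

  by generalized least squares with the AR(1) parameter φ profiled out
  of the restricted likelihood (gap-aware: corr = φ^Δmonths). Trends ω
  (units · year⁻¹) are classified `decreasing` / `none` / `increasing`
  at a two-sided α = 0.05. Temperature uses two annual harmonics;
  visibility and rainfall none.
* **Detectability** — the record length needed to detect a trend ω₀ with
  probability 0.90 at the 2σ level:
  n\* = [(3.3·σ_N/|ω₀|)·√((1+φ)/(1−φ))]^{2/3} years.
* **Covariates** — fetch-limited wave exposure from a 32-sector wind
  rose, current speed, human-population change in a 1°-diameter buffer,
  and AR(1)-corrected rainfall trends.
* **Category model** — multinomial (softmax) regression of trend
  categories on covariates (reference class `none`), drop-one
  likelihood-ratio tests, predicted-probability curves, and
  habitat-association chi-squared tests.
* **Synthetic data** — generators for single series, covariate-linked
  station networks, and a full synthetic emulation of the CARICOMP
  network (real station metadata, simulated measurements) so every
  stage is testable without external data.

## Worked example

```r
library(caritrend)

sim <- simulate_caricomp_like(seed = 1)   # synthetic 48-station network
cfg <- pipeline_config(weekly = sim$weekly, metadata = sim$metadata,
                       covariates = sim$covariates, seed = 1)
res <- run_full_analysis(cfg)
res
#> caritrend pipeline result
#>   temperature: 28 stations | 2 decreasing, 21 none, 5 increasing
#>   visibility: 24 stations | 11 decreasing, 11 none, 2 increasing
```

Of the 48 simulated stations, 29 pass the long-term filter; the 28
analysable temperature series yield 5 significant increases (18%) and
the 24 visibility series 11 significant decreases — the planted
structure (5 increases, 10 decreases plus one type-I error) recovered
by the pipeline. A single station fit:

```r
fits <- attr(fit_trend_table(
  filter_long_term(aggregate_monthly(sim$weekly, "temperature"))$retained,
  n_harmonics = 2), "fits")
fits[["COLr"]]
#> AR(1)-GLS trend fit (211 months, 2 harmonic(s))
#>   level mu         27.1964
#>   trend omega       0.1027 per year (SE 0.0089, p = 5.358e-24)
#>   phi               0.3910
#>   sigma_N           0.4815 (innovation SD 0.4432)
#>   category: increasing
```

The reef at Chengue Bay warms by 0.10 °C · year⁻¹ in this simulation,
with monthly noise of SD 0.48 °C and one-month memory φ = 0.39. Which
stations would detect a 0.05 °C · year⁻¹ warming soonest?

```r
det <- res$detectability
head(det[order(det$years_needed), ], 4)
#>    station_id sigma_N   phi years_needed years_available
#> 16       MEXs   0.350 0.138         8.90            11.9
#> 15       MEXr   0.318 0.291         9.28            11.6
#> 28       VENs   0.508 0.302        12.80            17.8
#> 9        COLr   0.482 0.391        13.21            17.6
```

The quiet Puerto Morelos stations (MEXs, MEXr) need only ~9 years of
monthly data; noisier, more autocorrelated stations need decades.

A thin command-line wrapper with `simulate`, `fit`, and `run`
subcommands lives at `inst/scripts/caritrend.R`.

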