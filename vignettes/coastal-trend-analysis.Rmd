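---
title: "Methods: trend detection in coastal monitoring time series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trend detection in coastal monitoring time series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(caritrend)
```

## The problem

Coastal monitoring networks such as CARICOMP collect weekly measurements
of water temperature (°C), salinity, and visibility (Secchi distance, m)
at fixed stations in reef, seagrass, and mangrove habitats. Two
questions drive the analysis in this package: has a station warmed or
lost water clarity over its record, and what station-level conditions
(wave exposure, currents, human population growth, rainfall trends)
explain where clarity is being lost? Both questions are complicated by
the data's serial correlation: consecutive monthly values remember each
other, so ordinary regression drastically overstates trend significance.

## The trend model

Weekly values are averaged into calendar-month means, and only series
with at least three years of span *and* at least 30 monthly records are
fitted (both thresholds inclusive; span is counted from first to last
populated month). For a monthly value $y_t$ at month index $t$:

$$y_t = \mu + \frac{\omega}{12}\,t + S_t + N_t, \qquad
S_t = \sum_{j=1}^{J}\left[\beta_{1j}\sin\frac{2\pi j t}{12}
 + \beta_{2j}\cos\frac{2\pi j t}{12}\right],$$

$$N_t = \phi\,N_{t-1} + \epsilon_t, \qquad
\epsilon_t \sim \mathcal{N}(0, \sigma_\epsilon^2),$$

so $\omega$ is a rate per year while $t$ counts months. Temperature uses
$J = 2$ annual harmonics; visibility and rainfall use $J = 0$. The
marginal noise SD is $\sigma_N = \sigma_\epsilon/\sqrt{1-\phi^2}$.

Estimation is generalized least squares with $\phi$ profiled out of the
Gaussian likelihood: a 27-point grid on $[-0.3, 0.99]$ followed by
bounded refinement to tolerance $10^{-6}$. Because series have missing
months, the AR(1) correlation is applied through the Markov property,
$\mathrm{corr}(N_{t_i}, N_{t_j}) = \phi^{|t_i - t_j|}$ with the exponent
equal to the true month gap; the whitening transform is therefore exact
and $O(n)$, and the test suite verifies it against explicit inversion of
the full covariance matrix to $10^{-8}$.

**REML rather than ML.** The profile criterion is the restricted
likelihood by default. At the record lengths typical of this kind of
monitoring (a decade or two), ML's downward bias in $\hat\phi$ is large
enough to push the trend test's type-I error above its nominal band
(about 0.084 versus a nominal 0.05 on trendless $\phi = 0.6$ series of
120 months); REML brings it to about 0.067. ML remains available via
`fit_ar1_gls(..., method = "ML")`.

Inference on $\omega$ uses the GLS coefficient covariance with the
df-corrected residual variance and a $t$ reference with $n - p$ degrees
of freedom ($p$ = number of regression coefficients, excluding $\phi$).
A station is classified `increasing` when $p < \alpha$ and
$\hat\omega > 0$, `decreasing` when $p < \alpha$ and $\hat\omega < 0$,
and `none` otherwise; $\alpha = 0.05$ two-sided throughout.

Initial values are immaterial under profiling (the GLS solution is
closed-form given $\phi$), which is why profiling was chosen: it is
deterministic and cannot wander to a secondary optimum the way a joint
quasi-Newton search can.

## Detectability

For a complete monthly record of $n$ years, the trend standard error is
approximately

$$\mathrm{SE}(\hat\omega) \approx \frac{\sigma_N}{n^{3/2}}
 \sqrt{\frac{1+\phi}{1-\phi}},$$

and the record length at which a true trend $\omega_0$ is detected
($|\hat\omega|/\mathrm{SE} > 2$) with probability 0.90 is

$$n^* = \left[\frac{3.3\,\sigma_N}{|\omega_0|}
 \sqrt{\frac{1+\phi}{1-\phi}}\right]^{2/3} \text{years}.$$

`years_to_detect()` evaluates this and `detectability_table()` applies
it per station using each station's fitted $(\sigma_N, \phi)$, with
negative fitted $\phi$ floored at zero (the formula's domain; negative
memory only shortens detection). The suite checks the formula against
simulation: empirical power at the $n^*$ record length is 0.90 within
Monte-Carlo error for several $(\sigma_N, \phi, \omega_0)$
configurations.

## Station covariates

* **Wave exposure** combines a 32-sector wind rose (frequency and mean
  speed per 11.25° sector) with per-sector fetch (km, capped at 500 km
  by default — open-ocean wave growth saturates). Per sector the
  deep-water fetch-limited growth law
  $H = 1.6\times10^{-3}\,U\sqrt{F/g}$ gives a significant wave height,
  converted to energy density $E = \rho g H^2/16$ (J/m²) and weighted by
  sector frequency. The growth relation is pluggable
  (`height_fun` argument) since different wave climates justify
  different empirical laws. Exposure is linear in the frequencies and
  monotone in fetch, both verified as properties.
* **Current speed** is consumed as a precomputed per-station scalar
  (m/s); no ocean-model I/O is attempted.
* **Population change** sums persons (density × cos-latitude-corrected
  cell area) over grid cells whose *centers* fall inside a 1°-diameter
  planar buffer around the station, year 2000 minus 1990. Cell-center
  membership was chosen over area weighting because it is simple,
  deterministic, and exactly testable by enumeration.
* **Rainfall trend** applies the $J = 0$ trend model to monthly
  precipitation (mm/month), returning a rate per year with its p-value.

## Modelling trend categories

Because a non-significant trend's magnitude is uninformative, the
response is the three-way category, and a multinomial (softmax)
regression links it to covariates with `none` as the reference class —
the two fitted logits read directly as "toward decreasing" and "toward
increasing". Fitting is full Newton–Raphson with step-halving (the
log-likelihood is verified never to decrease) to a gradient norm below
$10^{-8}$; covariates are standardized internally and coefficients
reported on both scales. Per-covariate inference is a drop-one
likelihood-ratio test on $K-1$ degrees of freedom, with a Wald
chi-squared reported alongside — at 24–28 stations one p-value per
covariate is the honest resolution.

Networks this small separate easily: with 4 covariates and ~24
stations a covariate pattern can predict a class perfectly, sending
coefficients to infinity. The fit flags any standardized coefficient
beyond 15 as quasi-separation, and the pipeline then refits with a
small ridge penalty (default 1 on standardized slopes, flagged
`ridged`) so the reported tests compare finite optima. Exactly
collinear columns are detected up front and excluded with a record
rather than crashing.

## The synthetic generator

`simulate_weekly_series()` realizes the trend model generatively:
stationary AR(1) monthly noise (including the stationary start),
harmonic seasonality, a linear trend, month-level gaps missing
completely at random, and weekly observations equal to the month's
latent value plus independent jitter (SD defaulting to
$0.5\,\sigma_\epsilon$ — the analysis consumes monthly means, so weekly
micro-structure is unconstrained; the default keeps it subordinate to
the monthly noise). `simulate_network()` adds the covariate layer: true
multinomial coefficients generate category probabilities, categories
draw trend magnitudes (zero for `none`), and every station emits weekly
records.

`simulate_caricomp_like()` is a synthetic emulation of the CARICOMP
network itself: the 29 published long-term stations keep their real
ids, habitats, coordinates and record spans, 19 synthetic short-record
stations complete the 48-station network (20 reef, 19 seagrass, 9
mangrove), one long-term seagrass station records Secchi only (so 28
temperature and 24 visibility series are analysable — mangroves carry
no Secchi record at all), and trends are planted at the published
tallies (five temperature increases and one decrease; ten visibility
decreases and two increases). Planted magnitudes are three times the
detectability bound for each station's record length, so the planted
category is recoverable by construction; the Puerto Morelos stations
are given the quietest noise (shortest years-to-detect, about 9–10
years) and the eastern Venezuela stations the noisiest. Synthetic
covariates are drawn conditional on the planted visibility category
(clarity loss co-occurs with population growth, low exposure, weak
currents, and wetting rainfall).

What the emulation does *not* reproduce: real operator and instrument
changes, non-AR(1) noise (regime shifts, El Niño-scale excursions),
spatially correlated noise between nearby stations, seasonality in
visibility, and informative (non-random) gap patterns. Passing tests on
the emulation therefore demonstrate that the pipeline's statistics are
internally correct at realistic problem sizes, not that any particular
real-world station trends as planted.

## Numerical choices and problem sizes

* $\phi$ grid: 27 points on $[-0.3, 0.99]$, then `optimize()` on the
  bracketing interval, tolerance $10^{-6}$; the reported likelihood is
  verified to be the profile maximum.
* Numerically interpolated series (residual SD below
  $10^{-8}(1 + |\hat\mu|)$) are classified by comparing $|\hat\omega|$
  to the same floor instead of a meaningless $t$ ratio.
* Validation sizes, chosen to estimate each rate to adequate
  Monte-Carlo precision: 2,000 replicates for type-I calibration
  (rejection-rate SE ≈ 0.005), 500 for trend CI coverage, 1,000 per
  configuration for detection power, 500 for the null distribution of
  the drop-one LRT, and 200 for multinomial Wald coverage at 200
  stations.
* All simulations are seeded; identical seeds reproduce outputs
  bit-exactly, and the pipeline writes a config-hash manifest so reruns
  can be compared byte for byte.

## Known limitations

* The AR(1) assumption is the simplest serial-correlation form; longer
  memory (ARMA, long-range dependence) would widen true uncertainty
  beyond what is reported.
* The detectability formula assumes complete monthly records; with
  gaps it is mildly optimistic.
* Drop-one LRTs on ridge-stabilized fits compare penalized optima; the
  chi-squared reference is then approximate (flagged in output).
* Visibility is modelled without harmonics; stations with genuinely
  seasonal clarity will show inflated $\sigma_N$ and conservative
  trend tests.
* The multinomial model ignores spatial dependence between stations
  and uncertainty in the first-stage category assignments.
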