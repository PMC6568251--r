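---
title: "Quantifying soil moisture-temperature coupling with vector autoregressions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying soil moisture-temperature coupling with vector autoregressions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(soilcoupling)
```

## The problem

Soil temperature and volumetric soil moisture interact through evaporation,
vapour transport, root water uptake and the moisture dependence of thermal
conductivity and heat capacity. Mechanistic soil-plant-atmosphere models
resolve these couplings explicitly but demand many hard-to-measure
parameters and say little about stochastic variability or the *time lag*
with which one variable answers a disturbance in the other. When all one
has is a pair of hourly sensor series per depth, a purely data-driven
route is attractive: treat the deseasonalized pair as a stationary
bivariate stochastic process, fit a vector autoregression (VAR), and read
the coupling off impulse-response functions and Granger causality tests.

`soilcoupling` implements that route end to end for series measured at
representative depths of a cropped profile (topsoil around 10 cm, subsoil
around 30 cm, substratum around 90 cm), together with a fully seeded
synthetic generator so every stage can be validated against known ground
truth.

## The model chain

### Seasonal differencing

Hourly soil series carry a strong diurnal cycle. With period $S = 24$ h,
`seasonal_difference()` forms $y_t = x_t - x_{t-S}$, which annihilates any
exactly 24-periodic component. The first $S$ parent values are retained so
the transform is exactly invertible (`reconstruct_series()`), and the
differenced series is $S$ observations shorter and starts one day later.
A 163-day December-May record of 3,912 hourly values therefore yields
3,888 deseasonalized values.

### Stationarity screening

VAR inference presumes weak stationarity (constant mean and variance,
autocovariance depending only on the lag). `adf_test()` screens each
deseasonalized series with the augmented Dickey-Fuller regression

$$\Delta y_t = \rho\, y_{t-1} + \sum_{i=1}^{q} \beta_i \Delta y_{t-i}
  \;[+\,c\;][+\,\delta t\;] + \varepsilon_t,$$

in three variants: no deterministic term (`"ar"`), constant (`"ard"`),
constant plus trend (`"ts"`). The t-statistic of $\hat\rho$ is compared
with MacKinnon response-surface critical values, and p-values come from the
matching published normal-quantile polynomials; a seeded Monte-Carlo
evaluation of the null (a driftless random walk) is available as an
independent check (`method = "simulation"`). The augmentation lag $q$ is
the smallest one whose regression residuals pass a Ljung-Box whiteness
test at 24 lags ($p > 0.05$); if none passes by `q_max`, the
BIC-minimizing lag is used with a warning. The pipeline's default variant
is `"ar"`: deseasonalized series are near-zero-mean by construction, and
the no-constant critical values ($-2.566/-1.941/-1.617$ at $n \approx
3{,}888$) are the ones field reports for this kind of data print. The
variant remains configurable. p-values below $10^{-3}$ are printed as
"< 0.001"; the numeric value is kept untruncated.

By default the pipeline refuses to fit a VAR when a series is not judged
stationary at the 10% level; `allow_nonstationary = TRUE` downgrades the
stop to a warning for exploratory use.

### VAR fitting and lag-order choice

`fit_var()` estimates
$y_t = c + \Phi_1 y_{t-1} + \cdots + \Phi_p y_{t-p} + e_t$
by equation-wise least squares on the common regressor set — the
conditional Gaussian maximum-likelihood estimator. The residual covariance
uses the ML divisor $n$, so the maximized log-likelihood has the closed
form $-(n/2)(m\log 2\pi + \log\det\hat\Sigma + m)$. The intercept is
always estimated; published coefficient listings sometimes omit it, which
we treat as presentation, not as a different model.

`lag_selection_table()` fits $p = 1..p_{\max}$ (default 8) on a common
sample — the first $p_{\max}$ rows are reserved for every fit — so that
$\mathrm{AIC} = 2k - 2\ell$ and $\mathrm{BIC} = k\log n - 2\ell$ are
comparable across orders, with $k = m(mp + 1)$ counting intercept and lag
coefficients but not the covariance. When AIC and BIC disagree on the
minimizing order, `select_lag_order()` takes the smaller of the two: fewer
parameters, smaller estimation error.

The observation count $n$ entering the BIC penalty is a reporting
convention and is kept explicit. Reconciling published per-lag criteria
tables for this system against their printed log-likelihoods shows their
BIC arithmetic used $n = 3{,}864$ — one day fewer than the 3,888
deseasonalized observations; with $n = 3{,}864$ every printed row
reproduces to within print rounding, while $n = 3{,}888$ leaves
discrepancies up to 0.27 at high orders. The acceptance suite encodes the
reconciling convention.

### Stability

`stability_check()` builds the $mp \times mp$ companion matrix (top
block-row $[\Phi_1 \cdots \Phi_p]$, identity blocks on the subdiagonal)
and requires every eigenvalue modulus to be below one. Stability
guarantees the moving-average expansion converges, hence that impulse
responses decay and bootstrap bands are meaningful. The bundled reference
coefficient sets (`soil_reference_var()`) have maximum moduli 0.974,
0.962 and 0.997 at 10, 30 and 90 cm: stable, but close enough to the unit
circle that shocks persist for days — the essential feature of slow soil
dynamics.

### Impulse responses, intensity, time lag

With $\Psi_0 = I$, $\Psi_i = \sum_{s \le \min(i,p)} \Phi_s \Psi_{i-s}$,
`unit_shock_irf()` reports responses to a one-unit positive shock under
three identifications:

* **reduced** — unit shocks to the reduced-form errors ($\phi(i) = \Psi_i$);
* **cholesky** — orthogonalized shocks rescaled to unit own-impact;
  depends on variable ordering;
* **generalized** (default) — column $k$ is
  $\Psi_i \Sigma e_k / \sigma_{kk}$: the expected response to a unit shock
  in variable $k$ accounting for the correlation of the innovations, and
  invariant to variable order.

The generalized scheme is the default because field innovations of
moisture and temperature are contemporaneously correlated, and observed
response tables for this system show *both* contemporaneous
cross-responses nonzero — impossible under any single Cholesky ordering.

Two scalar summaries grade the coupling:

* **intensity** — `response_intensity()` returns
  $\max(0, \max_i \phi(i)) - \min(0, \min_i \phi(i))$, the gap between the
  clamped extremes, in units of the responding variable per unit shock. A
  one-signed curve's intensity is simply its largest magnitude.
* **time lag** — `response_time_lag()` returns the smallest horizon from
  which the curve stays within `epsilon_frac` (default 0.05) of the
  intensity of zero through the last computed horizon. "Approximates
  zero" needs an operational threshold; 5% of the intensity is that
  choice, and the fraction is an exposed parameter. A curve that has not
  settled by `H` returns `H + 1` flagged `censored`, matching the field
  reading "longer than `H` hours". The default horizon is `H = 120` h.

`bootstrap_bands()` adds pointwise percentile bands (default 90%) by
nonparametric residual resampling: recentred fitted residuals are redrawn
with replacement, a series is rebuilt from the fitted model, refit, and
its responses recomputed; unstable refits are discarded (a warning is
raised if more than 20% are). Bands are deterministic given the seed.
The default is $B = 1000$ replicates.

### Granger causality

`granger_f_test()` regresses $x_t$ on a constant, $p$ lags of $x$ and $p$
lags of $y$ (unrestricted, $\mathrm{RSS}_0$) and without the $y$ lags
(restricted, $\mathrm{RSS}_1$), both on the same rows, and forms

$$F = \frac{(\mathrm{RSS}_1 - \mathrm{RSS}_0)/p}
          {\mathrm{RSS}_0 / (T - 2p - 1)},$$

compared with $F(p,\,T-2p-1)$ critical values at 1, 5 and 10%. The
conclusion is temporal predictability, not mechanism. `granger_table()`
runs both directions; the lag default is the VAR's selected order, with
per-direction overrides because published decision tables for this system
imply direction-specific lags (their printed critical values correspond
to different numerator degrees of freedom per direction).

## The synthetic generator

`generate_dataset()` produces datasets with known truth, emulating the
phenomenology of a December-May winter-wheat season on loam:

* per depth, a deterministic part: baseline plus a slow piecewise-linear
  seasonal trend (cooling into mid-winter, warming into spring; gradual
  moisture drawdown) damped with depth, plus a cosine diurnal harmonic
  whose amplitude decays and phase retards with depth;
* a stationary bivariate VAR residual pair per depth (default truth: the
  `soil_reference_var()` coefficient sets) riding on a *seasonal
  integration*: the VAR draw $v_t$ enters as $r_t = v_t + r_{t-24}$, so
  period-24 differencing of the generated series returns $v_t$ *exactly*.
  This makes end-to-end recovery tests sharp: the pipeline's
  deseasonalized substrate is the VAR process itself, not a moving-average
  distortion of it;
* sporadic irrigation steps in moisture (default: two events in early and
  mid-March reaching depths up to 50 cm, jump then exponential decay with
  a 120-hour half-life).

The trend is piecewise-linear rather than harmonic deliberately: its
seasonal difference is a known constant per segment, which is testable.
Innovations are Gaussian, matching the ML framing; heavier-tailed options
are out of scope. Per-depth innovation standard deviations default to
(0.005, 0.015) at 10 cm, (0.01, 0.02) at 30 cm and (0.005, 0.01) at
90 cm (moisture %, temperature degC; correlation 0.3). These were chosen
from the stationary variance implied by the moving-average expansion of
the reference dynamics so that deseasonalized fluctuations sit at
field-realistic tenths of a unit and the level series stay well inside
the instrument ranges (moisture 0-100%, temperature -20 to 60 degC);
generation validates those ranges and fails loudly rather than clip.

What the generator does *not* emulate: sensor noise and quantization,
missing hours, rain events, non-Gaussian innovations, slow variance
changes across the season, and any physically based heat/water transport.
Tests passing on synthetic data therefore certify the *inferential
machinery* — they do not certify that a particular field dataset meets
the model's assumptions; the stationarity screen exists for that reason.

## Numerical choices and edge cases

* Rank-deficient regressor matrices raise classed `collinear` errors;
  degenerate residual covariances raise `degenerate` errors rather than
  producing silent pseudo-inverses.
* Timestamps are stored time-zone naive; only the strict one-hour spacing
  matters downstream. Missing hours are rejected by default; runs of at
  most two can be linearly interpolated behind an explicit flag, and the
  interpolation is reported.
* The residual covariance divisor is $n$ (ML). The unbiased $n-k$ variant
  would shift log-likelihoods but not coefficient estimates.
* `select_lag_order()` breaks AIC/BIC disagreement toward fewer
  parameters; ties within a criterion take the smaller order via
  `which.min`.
* Reference coefficient sets are printed to three decimals. For
  near-unit-root systems that rounding is consequential at long horizons:
  the 10 cm set's reduced-form cross response develops a large swing
  around one day after the shock that a smoothly decaying fitted model
  would not show. The sets are therefore treated as *generating truths*
  for synthetic data and stability checks, not as faithful reproductions
  of any particular fitted model's response surface.

## Validation scales and interpretation

The test suite validates each stage against independent oracles
(explicit normal equations and `lm()` for the regressions, `stats::ar.ols`
for VAR coefficients, `lmtest::grangertest` for the F statistic,
brute-force shocked-minus-baseline simulation for generalized responses,
Yule-Walker algebra for simulated autocovariances) and checks the
statistical guarantees at deliberately modest problem sizes chosen to
keep the default run fast: unit-root test size with 1,000 replicates at
$T = 500$; Granger size with 1,000 replicates at $T = 1000$ and power
with 200 replicates at $T = 500$; order recovery with a few dozen seeded
replicates at $T = 3000$.

One validation deserves a note. Coefficient recovery from the 10 cm
reference truth at $T = 4000$ is assessed on the *Monte-Carlo mean* of 20
seeded fits (every coefficient within $\pm 0.05$ of truth), not
per-replicate: the near-unit-root lag polynomial makes single-fit
elementwise errors of 0.05-0.12 typical at that sample size even though
the estimator is consistent (max error 0.007 at $T = 50{,}000$). The mean
criterion checks unbiasedness at the study scale; the consistency check
covers convergence.

## Limitations

Linearity is assumed throughout; regime shifts (irrigation, rain) enter a
fitted VAR as innovations, not structure, which inflates apparent noise
around events. Granger causality is predictive, not mechanistic. The ADF
variants cover no structural breaks, and no KPSS-style confirmation test
is included. Bivariate systems only: conditional (multivariate) causality
among several depths is out of scope.
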