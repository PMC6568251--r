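# soilcoupling

Data-driven analysis of the coupling between hourly soil temperature and
volumetric soil moisture in a cropped soil profile.

Agronomists and soil physicists who log paired temperature/moisture series
at depth (typical probes: 10 cm topsoil, 30 cm subsoil, 90 cm substratum)
often want to know *how strongly* and *with what delay* the two variables
answer disturbances in each other — an irrigation pulse, a cold front —
without calibrating a full mechanistic soil-plant-atmosphere model. This
package implements the stochastic alternative: treat the deseasonalized
pair at each depth as a stationary bivariate process and read the coupling
off a fitted vector autoregression.

The pipeline, per depth:

1. **Seasonal differencing** — remove the diurnal cycle with
   `y_t = x_t − x_{t−24}` (hourly data, period S = 24).
2. **Stationarity screen** — augmented Dickey–Fuller tests
   (`Δy_t = ρ y_{t−1} + Σ β_i Δy_{t−i} [+ c][+ δt] + ε_t`) in no-constant,
   drift, and trend variants, with MacKinnon response-surface critical
   values and p-values, and whiteness-based choice of the augmentation lag.
3. **VAR fit** — `y_t = c + Φ_1 y_{t−1} + … + Φ_p y_{t−p} + e_t` by
   conditional Gaussian maximum likelihood; lag order chosen on a common
   sample by AIC = 2k − 2ln L̂ and BIC = k ln n − 2ln L̂ with
   k = m(mp + 1), breaking disagreement toward parsimony.
4. **Stability** — all eigenvalues of the companion matrix inside the unit
   circle.
5. **Impulse responses** — unit-shock response curves φ_jk(i) over horizons
   0..120 h (reduced / Cholesky / order-invariant generalized scheme,
   default generalized), with residual-bootstrap percentile bands, plus the
   two field summaries: **intensity** (gap between zero-clamped curve
   extremes, units of the responder per unit shock) and **time lag**
   (horizon from which the curve stays within 5% of the intensity of zero).
6. **Granger causality** — both directions,
   `F = ((RSS₁ − RSS₀)/p) / (RSS₀/(T − 2p − 1))` against F(p, T − 2p − 1)
   at 1/5/10%.

A seeded synthetic generator (`synthetic_config()` / `generate_dataset()`)
produces coupled hourly profiles with known ground truth — diurnal
harmonics damped with depth, slow seasonal trend, stationary VAR residuals
on a seasonal integration (so differencing recovers them exactly), and
irrigation step events — making every stage testable without field data.

## Worked example

```r
library(soilcoupling)

ds     <- generate_dataset(synthetic_config(days = 160, seed = 1))
report <- run_analysis(ds, analysis_config(depths = 10, boot = 0))
report
#> Soil coupling analysis report (1 depth(s))
#>
#> == 10 cm ==
#>   chosen lag order: 4 (AIC min at p = 5, BIC min at p = 4; taking the more parsimonious p = 4)
#>   stability: max |eigenvalue| = 0.9479 (stable)
#>   intensity MCSD10->STSD10: 0.0484; STSD10->MCSD10: 0.5063
#> # A tibble: 6 x 5
#>   direction        level f_stat critical_value conclusion
#>   <chr>            <dbl>  <dbl>          <dbl> <chr>
#> 1 STSD10 -> MCSD10  0.01  0.495           3.32 No
#> 2 STSD10 -> MCSD10  0.05  0.495           2.37 No
#> 3 STSD10 -> MCSD10  0.1   0.495           1.95 No
#> 4 MCSD10 -> STSD10  0.01  1.99            3.32 No
#> 5 MCSD10 -> STSD10  0.05  1.99            2.37 No
#> 6 MCSD10 -> STSD10  0.1   1.99            1.95 Yes
```

Reading the output: the deseasonalized pair at 10 cm passed the
stationarity screen (both series, no-constant ADF); the selected VAR(4) is
stable but persistent (largest companion modulus 0.948, so shocks decay
over days); a 1% moisture shock moves temperature by at most 0.0484 °C
over the 120-hour window (`MCSD10->STSD10` intensity), while a 1 °C
temperature shock moves moisture by up to 0.51%; and in this synthetic
draw past moisture improves temperature prediction only at the permissive
10% level (F = 1.99 against the 1.95 critical value), with no evidence in
the reverse direction. Curves and bands plot with `autoplot(res$irf)`, and
`tidy()`/`glance()` methods turn every fitted object into tibbles:

```r
glance(report$depths[["10"]]$model)
#> # A tibble: 1 x 7
#>       p     n loglik     aic     bic max_modulus stable
#>   <int> <int>  <dbl>   <dbl>   <dbl>       <dbl> <lgl>
#> 1     4  3812 12305. -24573. -24461.       0.948 TRUE
```

`soil_reference_var()` bundles published near-unit-root coefficient
estimates for the three depths of a winter-wheat loam profile; they serve
as the generator's default truth and as stability fixtures.

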