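# longlag

Estimating **long-term (months-to-years) environmental exposure effects from
case-only daily time series** — death certificates, hospitalization records —
with constrained distributed-lag quasi-Poisson regression.

Time-series regression is standard for *short-term* exposure effects. For
long-term effects the usual seasonality/trend adjustment, a natural cubic
spline of running time with several df per year (`NCS(t, p df/year)`),
absorbs nearly all low-frequency exposure variation and inflates the
standard error of the cumulative effect, sometimes by orders of magnitude.
`longlag` implements the alternative adjustment family

```
NCS(doy, p df) + I(year) + NCS(week, q df) + NCS(month, r df)      # "p,q,r"
```

inside the model

```
log E[Y_t] = alpha + sum_{l=0}^{L} beta_l X_{t-l} + f(Z) + g(t),   beta = W theta
```

with the per-lag coefficients constrained to a smooth spline curve over
`log(lag+1)` and inference on the overall cumulative coefficient
`beta_bar = sum_l beta_l`, reported as the percent increase per
10 µg/m³: `100 (exp(10 beta_bar) - 1)`.

The package also provides: residual-exposure-variance overfitting
diagnostics and the predicted SE-inflation ratio; a synthetic daily
generator (seasonal lognormal exposure at two concurvity levels, Poisson
outcomes driven by lag patterns with mortality displacement); a Monte-Carlo
harness reporting bias, SD of estimates and 95% CI coverage per adjustment
method; seasonality-deviation dummy sensitivity analyses; and two-stage
multivariate random-effects pooling of city-specific lag coefficients
(fixed / method-of-moments / ML).

## Worked example

```r
library(longlag)

cfg <- sim_config(n_years = 8, burn_in_days = 730, concurvity = "low", pattern = 1)
dat <- simulate_series(cfg, seed = 1)          # ~10 years of daily data
attr(dat, "truth")$beta_bar
#> [1] 0.01

fit <- dlm(dat, time_spec = "10,5,5", lag = c(0, 730), lag_df = 5)
fit
#> Constrained distributed-lag Poisson model
#>   lags 0..730 via 5 reduced coefficient(s); time basis: 10,5,5
#>   n used = 2922, dispersion = 0.982 (estimate), deviance = 2840.9
#>   overall cumulative coefficient: 0.01107 (SE 0.005151)

cumulative_effect(fit)
#> Cumulative effect over lags 0..730
#>   beta_bar = 0.0110657 (SE 0.00515), 95% CI [0.000969513, 0.0211618]
#>   percent increase per 10 ug/m3: 11.70% [0.97, 23.57]
```

The truth (0.01 per µg/m³, i.e. a 10.5% increase per sustained
10 µg/m³) lies well inside the interval. The same fit with the
conventional running-time spline shows the overfitting problem — the point
estimate is useless and the SE nearly two orders of magnitude larger:

```r
cumulative_effect(dlm(dat, time_spec = "t:10/yr", lag = c(0, 730), lag_df = 5))$se
#> [1] 0.3707101
```

Compare adjustment methods by simulation (here a small smoke run; the
package-scale evaluation uses 50–200 replicates):

```r
reproduce_table2(n_reps = 5, n_years = 8, seed = 1)
```

Two-stage multi-city workflow:

```r
cities <- generate_multicity(sim_config(n_years = 4, burn_in_days = 60, lag_max = 60),
                             n_cities = 7, heterogeneity_sd = 5e-4, seed = 2)
ests <- lapply(names(cities), function(cc)
  as_city_estimate(dlm(cities[[cc]], "4,2,2", lag = c(0, 60), lag_df = 4), cc))
pooled <- pool(ests, method = "ml")
pooled_cumulative(pooled, lag_constraint(60, 4))
```

A thin command-line interface over the same functions lives at
`inst/cli/longlag.R` (subcommands `simulate`, `fit`, `reproduce-table2`,
`deviations`, `pool`).

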