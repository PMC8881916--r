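# fishdyn

Size-structured population dynamics of stream fish from length-frequency
monitoring data.

## What problem this solves, and for whom

Freshwater monitoring programs (electrofishing, one pass per site-year)
produce long, patchy time series of fish counts and body lengths.  For
population ecologists and managers, two questions matter: **what drives
each local population** — density dependence, recruitment, survival
between size classes, or water temperature — and **whether those drivers
follow a biogeographic pattern**, a gradient along elevation/latitude
(*range-shift* hypothesis) or along the distance to the species'
geographic range center (*abundant-center* hypothesis).

`fishdyn` implements the complete analysis chain:

1. **Size-class splitting** — per-event two-normal mixture on lengths
   (EM), class boundary at the density crossing point, and a
   probabilistic status classifier (length, event size, degree-days
   above 12 °C) calibrated on clearly bimodal events and validated by
   repeated split-sample cross-validation (Cohen's κ).
2. **Covariates** — z-scored mean and intra-annual variability of water
   temperature between consecutive sampling occasions, plus their
   squares; haversine distances to a supplied range center.
3. **Hierarchical Bayesian state model** — for log-abundances
   `X0 (0+)` and `X1 (>0+)` with sampling-area offsets `S`:

   ```
   X0[i,t] ~ N(a0_i + b0_i * X1[i,t]/log S[i,t] + sum_j g0_ij U[j,i,t]
               + log S[i,t],                                   sd0)
   X1[i,t] ~ N(a1_i + X1[i,t-1] + b1_i * X1[i,t-1]/log S[i,t-1]
               + d1_i * X0[i,t-1]/log S[i,t-1] + sum_j g1_ij U[j,i,t]
               + log(S[i,t]/S[i,t-1]),                         sd1)
   ```

   a modified stochastic Gompertz model: `a1` is a productivity rate,
   `b1` density dependence, `d1` apparent survival, `b0` apparent
   recruitment, `g` temperature effects.  All 13 site coefficients are
   hierarchical (`theta_i ~ N(mu, sigma)`) with `N(0,10)` priors on the
   means and half-Cauchy priors on all SDs.  Fitting is by a
   purpose-built conjugate Gibbs sampler (RcppArmadillo) with latent
   imputation of missing years; diagnostics include the Gelman–Rubin
   statistic, HPD intervals, posterior overlap and χ² posterior
   predictive checks.
4. **Elasticities** — `e = ((θ_per − θ_ori)/θ_ori)/0.10`: proportional
   change of projected log-abundance per 10% proportional change of each
   parameter family (linear + quadratic temperature terms moved
   together), from posterior-median coefficients.
5. **Spatial model selection** — per family, AIC over four OLS models of
   site-level elasticities (null; quadratic elevation; quadratic
   distance-to-center; quadratic latitude), with adjusted R² and
   likelihood-ratio tests.

A first-class synthetic-data generator (`generate_sites()`,
`generate_parameters()`, `simulate_abundances()`, `simulate_lengths()`,
`inject_missingness()`) reproduces the statistical structure of the
monitoring data, so the entire pipeline runs and is tested offline.
See the methods vignette (`vignettes/fishdyn-methods.Rmd`) for the
modelling choices and their rationale.

## Worked example

```r
library(fishdyn)

# a synthetic study: 20 sites monitored for 18 years
sites  <- generate_sites(20, seed = 1)
truth  <- simulation_truth(seed = 2)          # ground-truth hyper-parameters
params <- generate_parameters(truth, sites)
U      <- generate_covariates(sites, 18, seed = 3)
panel  <- simulate_abundances(params, U, areas = 500, T = 18,
                              x0 = rep(4.5, 20),
                              process_sds = truth$process_sds, seed = 4)
panel  <- inject_missingness(panel, 0.08, max_consecutive = 3, seed = 5)

# fit the hierarchical model (reference chain geometry scaled down 2x)
model <- build_model(panel, U)
draws <- fit_popdyn(model, chains = 3, iterations = 5500,
                    burn_in = 500, thin = 5, seed = 6)
s <- summary(draws)
subset(s, parameter %in% c("mu[alpha1]", "mu[beta1]", "mu[delta1]",
                           "proc_sd0", "proc_sd1"))
#>     parameter median hpd_lower hpd_upper rhat
#> 7  mu[alpha1]   1.61     1.197      2.01    1
#> 8   mu[beta1]  -2.12    -2.496     -1.79    1
#> 9  mu[delta1]   0.43     0.039      0.85    1
#> 27   proc_sd0   0.39     0.358      0.42    1
#> 28   proc_sd1   0.24     0.220      0.27    1
```

The generating values (`mu[alpha1]` 1.5, `mu[beta1]` −2.0, `mu[delta1]`
0.4, process SDs 0.4/0.25) sit inside every 95% HPD interval, and all
R-hat values are at 1: the sampler recovers the world it was given.

```r
posterior_predictive_check(draws, model)
#> posterior predictive p: 0+ 0.49, >0+ 0.50    (≈ 0.5 = good fit)

med <- posterior_median_params(draws)
el  <- elasticity_analysis(med$theta, panel, U)
round(el$species_mean, 3)
#>  beta0 tmean0  tvar0 alpha1  beta1 delta1 tmean1  tvar1
#>  0.185 -0.009 -0.011  2.581 -2.734  0.614 -0.010  0.000
```

Read: a 10% change in density dependence (`beta1`) moves projected >0+
log-abundance by −27.3% on average, productivity (`alpha1`) by +25.8%,
while temperature families move it by under 0.2% — biotic factors
dominate, the qualitative signature this kind of analysis looks for.

```r
sites$distance <- distance_to_center(sites, center = c(2.5, 46.5))
fits <- lapply(rownames(el$site_mean), function(f)
  fit_candidates(data.frame(site_id = el$sites, value = el$site_mean[f, ]),
                 sites))
names(fits) <- rownames(el$site_mean)
select_best(fits)
#> Spatial model selection across 8 parameter families
#>   family aic_null aic_elevation aic_distance aic_latitude best_model adj_r2 ...
#> 1  beta0 -59.6084      -64.4101     -55.6795     -56.4683  elevation 0.2803
#> 2 tmean0 -61.9881      -85.0150     -58.7190     -59.2682  elevation 0.7106
#> ...
#> wins - range-shift: 5 | abundant-center: 2 | null: 1
#> verdict: range-shift
```

Temperature-family elasticities track elevation (the synthetic
temperature field is elevation-driven), so the selection lands on the
range-shift side — an end-to-end illustration, not an empirical claim
about any real species.

`run_pipeline(run_config(seed = 1))` executes all stages in order
(simulate → split-sizes → covariates → filter → fit → elasticity →
spatial) and writes per-stage CSV/JSON outputs plus a manifest with
seeds, file hashes and record counts.

## Acceptance script

`scripts/acceptance.R` re-runs the package's full computation from
scratch — synthetic study generation, size-class splitting with
classifier cross-validation, covariate construction, eligibility
filtering, the hierarchical fit at the reference chain geometry
(3 × 11,000, burn-in 1,000, thinning 10), elasticity analysis and
spatial model selection — and writes its JSON report:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

All randomness derives from `--seed`; a run takes about two minutes on
one CPU.
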