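# dynocc

Multi-season (dynamic) occupancy analysis for landscape-scale acoustic
monitoring campaigns — the kind of data the North American Bat Monitoring
Program (NABat) produces: night-by-night species detection records on large
(10×10 km) grid cells spread across ecoregions, surveyed with stationary
detectors and mobile transects over consecutive summers. It is written for
ecologists and biostatisticians who need the full chain from landscape
covariates to ranked candidate models, cross-validated predictive
performance, statewide occupancy maps and turnover rates, with every step
reproducible under a single seed.

## The model

For cell *i* in season *t*, a latent occupancy state `z[i,t] ∈ {0,1}`
evolves by colonization and extinction:

    z[i,1] ~ Bernoulli(psi[i,1]),  logit(psi[i,1]) = x_i' beta
    z[i,t+1] | z[i,t] ~ Bernoulli( z[i,t](1 - epsilon) + (1 - z[i,t]) gamma )

and nightly detections are conditional on presence (no false positives):

    y[i,j,t] | z[i,t] ~ Bernoulli( z[i,t] p[i,j,t] ),  logit(p) = w' alpha

Populations are closed within seasons and open between them. The package
provides:

* **Synthetic data** (`simulate_occu_dataset()`) — survey designs,
  correlated landscape covariates, latent dynamics and detection histories
  with the structure above, so the whole pipeline is testable without any
  field download.
* **Landscape metrics** (`percent_cover()`, `contagion()`,
  `edge_density()`) from categorical rasters in the ESRI ASCII grid text
  format, plus the Pearson `|r| > 0.7` screen (`pearson_screen()`) and
  covariate standardization with stored location/scale.
* **Bayesian fitting** (`fit_occu_mcmc()`) — Metropolis-within-Gibbs in
  C++: exact Bernoulli full conditionals for `z`, adaptive random-walk
  Metropolis for the logit-scale coefficients under Normal(0, 10) priors,
  conjugate Beta draws for `gamma`/`epsilon` under Uniform(0,1) priors; a
  closed-form marginal likelihood (`marginal_cell_loglik()`); R-hat
  diagnostics and 95% credible-interval significance flags.
* **Model selection** — first-principles WAIC on per-cell marginal
  pointwise log-likelihoods, ΔWAIC / relative likelihoods / weights, the
  ≤ 2.0 closely-competing rule, and region-constrained 5-fold
  cross-validated AUC (66% training; 38 cells split 25/13).
* **Inference products** — predicted occupancy grids over any cell universe
  (e.g. all 893 statewide cells), derived second-season occupancy
  `psi2 = psi1(1−ε) + (1−psi1)γ`, and colonization / extinction / turnover
  summaries with credible intervals.
* **Orchestration** (`run_pipeline()`) — the two-stage procedure: select
  detection covariates with occupancy held at intercept-only, then fit the
  13-model a priori occupancy candidate set (11 ecological models + null +
  global) with those detection covariates fixed.

## Worked example

```r
library(dynocc)

sim <- simulate_occu_dataset(
  n_cells = 38, seed = 11,
  beta  = c(`(Intercept)` = 0.3, Forest = 0.8),   # per-SD logit effects
  alpha = c(`(Intercept)` = 0.5, duration = 0.4),
  gamma = 0.2, epsilon = 0.1)

data <- build_occu_data(sim$detections, sim$covariates,
                        occ_covariates = "Forest",
                        det_covariates = "duration")
fit <- fit_occu_mcmc(data, mcmc_config(n_chains = 3, n_burnin = 500,
                                       n_sampling = 2000, thin = 4, seed = 12))
summarize_posterior(fit)
```

```
         parameter   mean  lower upper  rhat significant
  beta:(Intercept)  0.581 -0.081 1.244 0.999       FALSE
       beta:Forest -0.003 -0.718 0.698 1.002       FALSE
 alpha:(Intercept)  0.698  0.454 0.942 1.000        TRUE
    alpha:duration  0.340  0.099 0.598 1.001        TRUE
             gamma  0.248  0.079 0.477 1.000        TRUE
           epsilon  0.113  0.027 0.253 0.999        TRUE

Mean occupancy by season:
 year  mean lower upper
    1 0.634 0.480 0.772
    2 0.653 0.501 0.781
```

Each row is a posterior mean with its 95% credible interval and
Brooks–Gelman–Rubin R-hat; `significant` flags intervals excluding zero. At
38 cells the forest effect is not resolvable (interval spans zero) — an
honest reflection of the design's power — while the detection model and the
dynamics are: cells colonize with posterior mean probability 0.25 and go
extinct with 0.11 between years. `waic(fit)` gives the ranking criterion
(here 457.8), and:

```r
turnover_summary(fit)
#   quantity  mean  lower upper
# 1    gamma 0.248 0.0793 0.477
# 2  epsilon 0.113 0.0266 0.253
# 3 turnover 0.130 0.1053 0.132
```

where `turnover` is the posterior fraction of cells whose latent state
changed between the two years.

The `analysis/` directory holds the same workflow as six numbered narrative
scripts (simulate → raster metrics → correlation screen → detection-model
selection → occupancy-model selection with cross-validation → statewide
prediction and turnover), each writing its tables under `results/`. Run them
in order from the repository root with `Rscript analysis/01_simulate.R` etc.

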