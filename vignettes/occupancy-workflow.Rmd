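---
title: "Multi-season occupancy modeling of landscape-scale acoustic monitoring data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-season occupancy modeling of landscape-scale acoustic monitoring data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

dynocc implements a complete, tested workflow for estimating where a species
occurs across a landscape from night-by-night acoustic detection records on
a grid of large survey cells, when detection is imperfect and occupancy can
change between years. The archetype is a NABat-style campaign: 10×10 km
cells allocated across ecoregions, each cell surveyed on up to four
consecutive stationary-detector nights plus two mobile-transect nights in
each of two summers.

## The model

For cell $i$ and season (year) $t$, the latent occupancy state
$z_{i,t} \in \{0,1\}$ follows

$$z_{i,1} \sim \mathrm{Bernoulli}(\psi_{i,1}), \qquad
  \mathrm{logit}(\psi_{i,1}) = \mathbf{x}_i^\top \boldsymbol\beta,$$

$$z_{i,t+1} \mid z_{i,t} \sim \mathrm{Bernoulli}\!\big(z_{i,t}(1-\varepsilon) + (1-z_{i,t})\,\gamma\big),$$

with constant colonization $\gamma$ and extinction $\varepsilon$.
Populations are closed within a season (each cell is surveyed within about a
week) and open between seasons. Detections on occasion $j$ are

$$y_{i,j,t} \mid z_{i,t} \sim \mathrm{Bernoulli}(z_{i,t}\, p_{i,j,t}), \qquad
  \mathrm{logit}(p_{i,j,t}) = \mathbf{w}_{i,j,t}^\top \boldsymbol\alpha,$$

so false positives are impossible: a cell-year with any detection is
occupied with certainty. Occupancy covariates $\mathbf{x}_i$ are landscape
summaries (ecoregion, percent cover of agriculture / development / upland
forest / forested wetland, contagion, forest and forested-wetland edge
density, stream length, road lengths by class); detection covariates
$\mathbf{w}$ are the nine survey-level variables (survey type, duration,
vegetation clutter, date, survey issue, temperature, humidity, wind, rain).

Two modeling choices were genuinely open and are fixed as follows. First,
covariates act on initial-season occupancy only, with $\gamma$ and
$\varepsilon$ constant: with two seasons of data, covariate-dependent
dynamics are not identifiable, and the constant-dynamics parameterization is
the smallest model that still separates colonization from extinction.
Second, Region is dummy-coded against a fixed alphabetical reference level
(Blue Ridge), so coefficients are reproducible; per-region occupancy means
are coding-invariant.

## Likelihood and sampler

The per-cell marginal likelihood sums the complete-data likelihood over all
latent paths $(z_1,\dots,z_T)$ by a forward recursion
(`marginal_cell_loglik()`), exactly and without sampling. The test suite
pins this closed form against brute-force path enumeration to $10^{-12}$ on
a thousand random instances.

`fit_occu_mcmc()` samples the posterior by Metropolis-within-Gibbs:

* $z_{i,t}$: exact Bernoulli full conditionals, with $z$ forced to 1
  wherever the cell-year has a detection. Occasions lost to weather or
  malfunction are simply absent from the detection product (missing at
  random), not imputed.
* $\boldsymbol\beta, \boldsymbol\alpha$: per-coordinate random-walk
  Metropolis under vague Normal(0, sd 10) priors on the logit scale.
  Proposal scales adapt in batches of 50 iterations during burn-in only
  (targeting 0.44 acceptance, with diminishing steps), then freeze, so the
  sampling phase is a fixed-kernel chain.
* $\gamma, \varepsilon$: the Uniform(0,1) priors are Beta(1,1), conjugate to
  the latent transition counts, so both are drawn from their exact Beta full
  conditionals rather than by Metropolis — a strictly lower-variance update
  for the same posterior.

The production schedule is 3 independent chains, 5,000 burn-in iterations,
25,000 sampling iterations, thinning by 4: 6,250 retained draws per chain,
18,750 in total. Chains start from overdispersed draws (coefficients
N(0,1), dynamics Uniform(0.2, 0.8)) under per-chain seeds derived from one
master seed, making every fit bit-reproducible. Convergence is monitored
with the Brooks–Gelman–Rubin statistic
$\hat R = \sqrt{\{(n-1)W/n + B/n\}/W}$ per monitored parameter
(coefficients, $\gamma$, $\varepsilon$; not the data-constrained $z$), with
the conventional 1.1 threshold; non-convergence is recorded and warned
about, never silently ignored, and never an exception — mirroring how such
fits are reported in practice.

## Model selection and evaluation

Selection is two-stage: detection covariates are chosen first (each
candidate fit with intercept-only occupancy, ranked by WAIC) and then fixed
for the occupancy stage, which fits the 13-model a priori set — 11
ecological models, the null, and a global model. Wetland-associated species
substitute F.Wet/F.Wet.ED for Forest/F.ED and omit F.Wet.ED from the global
model. Before fitting, continuous covariates are standardized (sample SD,
$n-1$) and screened: any pair with Pearson $|r| > 0.7$ may not co-occur in
one model, and the global model greedily drops the later-listed member of
any flagged pair (tertiary road length never enters, being collinear with
development and secondary roads).

WAIC is computed from first principles on the pointwise marginal
log-likelihood: the pointwise unit is the **cell** (seasons pooled), the
independent sampling unit, with latent states marginalized analytically at
every retained draw — the conditional-on-$z$ alternative is well known to be
unstable. $\mathrm{lppd} = \sum_i \log \overline{\exp \ell_{si}}$ (computed
with a max-shift for stability), $p_\mathrm{WAIC} = \sum_i
\mathrm{var}_s(\ell_{si})$, $\mathrm{WAIC} = -2(\mathrm{lppd} -
p_\mathrm{WAIC})$. Rankings report $\Delta$WAIC, relative likelihood
$e^{-\Delta/2}$, normalized weights, and the $\Delta \le 2$ closely
competing flag; ties keep input order.

Predictive performance uses k-fold cross-validated AUC: five random
partitions, 66% training (round-half-up, so 38 cells split 25/13), each
training set constrained to contain at least one cell per ecoregion, the
same partitions reused for every species and model. Test cell-years are
scored by posterior-mean occupancy and labeled by observed naive occupancy
(at least one detection) — the only observable label; with low detection
probability this biases AUC toward 0.5, a caveat inherited by any such
evaluation. AUC itself is the rank-based Mann–Whitney statistic with tie
half-credit, checked in the tests against all-pairs concordance counting and
against an established ROC package. AUC is computed only for models ranking
at or better than the null, matching the usual reporting rule; pooled-year
AUC is the headline with per-year values also emitted. A test fold whose
labels are single-class yields an undefined fold AUC, excluded from the mean
with a logged warning.

## Landscape metrics

Per-cell covariates can be supplied directly or computed from categorical
rasters (ESRI ASCII grid text format). Conventions are fixed so results are
bit-reproducible:

* Adjacencies use the 4-neighbourhood, double-count convention (each
  adjacent pixel pair counted once in each direction; $g$ symmetric, like
  pairs twice on the diagonal), landscape boundary excluded; NODATA pixels
  participate in nothing.
* Contagion: $\mathrm{CONTAG} = [1 + \sum_{i,k} q_{ik} \ln q_{ik} / (2\ln
  m)] \times 100$ with $q_{ik} = P_i\, g_{ik}/\sum_k g_{ik}$ and $0\ln 0 :=
  0$; undefined (a classed error) for single-class landscapes.
* Edge density: shared focal/non-focal boundary length divided by landscape
  area in hectares (m/ha).
* Whether contagion runs on aggregated or raw classes is a user choice via
  `class_map`; the default map aggregates pasture/hay + cultivated crops to
  Ag, all development intensities to Dev, upland forest to Forest, woody
  wetlands to F.Wet.

Spatial buffering of real cell geometries and vector processing of stream
and road layers are GIS preprocessing, out of scope: rasters represent the
already-buffered extent, and stream/road lengths enter as precomputed (or
simulated) columns.

## What the synthetic generator emulates — and what it does not

`simulate_occu_dataset()` reproduces the statistical structure the analysis
assumes: 38 cells over five ecoregions (each region guaranteed at least one
cell), two seasons, 4 stationary + 2 mobile occasions per cell-year
(configurable mixes emulate mobile-only or stationary-only cells), latent
colonization–extinction dynamics, Bernoulli detections conditional on the
latent state, and landscape covariates drawn from a correlated Gaussian with
the dependence the screen must catch (development with road classes at
0.75, secondary with tertiary roads, forested-wetland cover with its edge
density at 0.8) mapped onto realistic ranges. Survey covariate
distributions, which no field protocol specifies: continuous ones standard
normal (so generating slopes are per-SD effects, directly comparable to the
fitted, standardized coefficients), clutter categorical (0.5/0.3/0.2),
rain Bernoulli(0.15), survey issue Bernoulli(0.05); stationary nights last
about 11 h, mobile transects about 1.2 h; dates are uniform over mid-May to
mid-July. An occasion-missingness rate is exposed (default 0 — no field
value exists to default to), never dropping a cell-year entirely.

The generator does **not** emulate spatial autocorrelation between
neighbouring cells, GRTS spatially balanced sampling, observer- or
site-level heterogeneity beyond the modeled covariates, false-positive
identifications, or real geographic coordinates. Passing tests therefore
demonstrate the estimator's correctness under the model's own assumptions,
not robustness to their violation in real acoustic data.

## Numerical choices and scale

All likelihood work is in log space with `log1p`/max-shifted logsumexp;
detection probabilities at extreme logits are handled through
`-log1pexp(-x)`. The sampler core is C++ (Rcpp) using R's RNG, so results
are reproducible across machines under a seed. Raster smoothing ties keep
the current class; candidate-model WAIC ties keep input order; train-size
rounding is half-up.

Problem sizes in the tests and scripts are the package's own choices:
parameter-recovery uses 50 replicates of 200 cells at a reduced schedule (3
chains × 2,000 sampling iterations, thin 4), which recovers 95% CrI coverage
of every generating parameter at the nominal rate; the workflow scripts run
38-cell campaigns at the same reduced schedule; the statewide prediction
grid uses 893 cells. The production schedule (18,750 retained draws) is the
default of `mcmc_config()` and is exercised for its accounting, not run in
the tests.

## Known limitations

* Two seasons identify constant $\gamma$ and $\varepsilon$ but not
  covariate-dependent or autologistic dynamics.
* Reported turnover is the posterior fraction of cells whose sampled latent
  state changed between years; because "turnover" is sometimes reported as a
  single number and sometimes as the colonization/extinction pair, all three
  quantities are emitted so any convention is recoverable.
* No spatial dependence, false-positive, or multi-scale (point-within-cell)
  structure; no DIC/LOO alternatives to WAIC; no spatially blocked CV.
* CV labels are naive occupancy, so AUC is attenuated for species with low
  detection probability.
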