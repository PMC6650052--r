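---
title: "Methods: direct estimation of PM2.5-attributable mortality and life-expectancy loss"
author: "pm25life"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: direct estimation of PM2.5-attributable mortality and life-expectancy loss}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The estimation problem

Prospective cohorts measure the mortality risk of fine particulate matter
(PM2.5) in selected participants. A *direct* small-area alternative is to
relate county-level death rates to county PM2.5 concentrations over time,
adjusting for other determinants of mortality, and then to convert the
fitted concentration-response into counterfactual deaths and life
expectancy. `pm25life` implements that pipeline end to end: panel
construction, four spatiotemporal Poisson models fitted per sex and
five-year age group (18 groups, birth to 85+), counterfactual
attribution, abridged lifetables with old-age extension, and a
sociodemographic inequality regression. A synthetic county-panel
generator with known ground truth stands in for restricted
vital-registration microdata, so every stage is testable offline.

## The four models

For one sex and age group, deaths in county $c$ and year $t$ follow

$$y_{ct} \sim \text{Poisson}(N_{ct}\, e^{\eta_{ct}}),$$

with log death rate

$$\eta_{ct} = \alpha_0 + \beta_0 t + \nu_t
  \;[+\; \alpha_c \;[+\; \beta_c t]]
  \;+\; \gamma\,\mathrm{PM}_{ct}
  \;[+\; \textstyle\sum_{i=1}^{9}\theta_i X_{i,ct}]
  \;+\; \varepsilon_{ct}.$$

The four specifications differ only in adjustment: *unadjusted* (no
covariates, no county terms), *covariate* (nine time-varying covariates:
log per-capita income, poverty %, Black/African American %, high-school
completion %, urban %, unemployment %, log age-standardised lung-cancer
death rate as a cumulative-smoking proxy, mean temperature, mean relative
humidity), *covariate-and-county* (adds CAR county random intercepts;
the main model, which infers the PM association mainly from differential
changes over time, like a difference-in-difference design), and
*restrictive* (adds CAR county random time slopes, leaving only the
mortality residual net of county linear trends). $\gamma$ is the log
rate ratio per 1 μg/m³; rate ratios per 10 μg/m³ are `exp(10*gamma)`.

Components and priors:

* **Year** is centred at the panel mid-year, decorrelating $\alpha_0$ and
  $\beta_0$.
* **$\nu_t$** is a first-order random walk capturing nonlinear trend. It
  is constrained to sum to zero *and* to be orthogonal to the linear year
  term, so "common slope" and "nonlinear trend" are identified
  separately.
* **$\alpha_c,\beta_c$** follow intrinsic CAR (pairwise-difference)
  priors over the county adjacency graph with a sum-to-zero constraint
  per connected component. Both constraints are imposed by spectral
  reparameterisation: the field is expanded in the positive-eigenvalue
  eigenbasis of the graph Laplacian, which makes the prior proper and
  diagonal. Isolated counties (possible after merging) get exchangeable
  Gaussian coordinates sharing the CAR precision, since the intrinsic
  prior is undefined for degree-zero nodes.
* **$\varepsilon_{ct}$** is iid Gaussian overdispersion, one per
  county-year.
* Random-effect precisions carry Gamma(1, 0.001) priors (equivalently a
  logGamma prior on the log precision); fixed effects have zero-mean
  Gaussian priors with precision 0.001.

## Inference

The model is a latent Gaussian field with a Poisson likelihood. The
package fits it with a Laplace approximation: for given hyperparameters,
a Newton iteration finds the joint posterior mode of the latent field,
with the iid overdispersion block eliminated analytically so each step
solves a dense system in the structured block only (fixed effects + RW1
+ CAR coordinates, a few hundred unknowns even for 400 counties).
Hyperparameters (the log precisions) are estimated by maximising the
Laplace approximation to their marginal posterior; the latent field is
then summarised by the Gaussian approximation at the mode, and posterior
draws of $\gamma$ are taken from its marginal for downstream
uncertainty propagation. This mirrors the nested-Laplace approach
standard for such models and is orders of magnitude faster than MCMC,
which matters when 36 strata are fitted per model; correctness is
defined by parameter-recovery and interval-calibration properties, which
the test suite checks against the generator's ground truth and an
independent maximum-likelihood Poisson oracle. Empirical Bayes ignores
hyperparameter uncertainty; in calibration runs the resulting intervals
are slightly conservative for $\gamma$ (z-scores with standard deviation
about 0.9), because $\gamma$ is a fixed effect informed by many
county-years.

Degenerate designs (a PM field with no variation) are refused rather
than fitted. Non-convergence of either the Newton iteration or the
hyperparameter search flags the fit; it is never a silent success.

## From rate ratios to deaths and life expectancy

Under the log-linear model, setting exposure to a counterfactual
$\mathrm{PM}^{cf}$ multiplies expected deaths by
$e^{\gamma(\mathrm{PM}^{cf}-\mathrm{PM})}$, so averted deaths are
$D\,(1 - e^{\gamma\Delta})$ with $\Delta = \mathrm{PM}^{cf}-\mathrm{PM}$
— the exact counterfactual-rate form, not an $(RR-1)/RR$ table
approximation. Two scenarios are built in: the *floor* scenario (every
county at 2.8 μg/m³, the lowest observed county concentration) and the
*reduction* scenario (1999 deaths had each county already been at its
2015 concentration). Attribution is applied per posterior draw of each
stratum's $\gamma$ and aggregated draw-by-draw to county and national
totals; strata are fitted independently, so their draws are treated as
independent. Observed deaths are held fixed: the intervals propagate the
PM coefficient's uncertainty only.

Life expectancy uses abridged lifetables on the 18 age groups with
$q_x = n m_x / (1 + (n - a_x) m_x)$, $n = 5$, $a_x = 2.0$ for ages 0-4
(childhood deaths concentrate early in the interval; the age structure
has no separate infant group) and $a_x = 2.5$ otherwise. The open 85+
group is expanded by the Kannisto-Thatcher method: a logistic hazard
$\mu(x) = a e^{bx}/(1+a e^{bx})$ is fitted to ages 60-84 on the logit
scale, and its level is rescaled so the stationary-population mean rate
over the extension reproduces the observed 85+ rate; extension runs in
5-year bands to an open 110+ interval, and the logistic form keeps every
extended hazard below 1/year. Non-increasing old-age rates trigger a
flagged fallback to a constant extension. Counterfactual lifetables
subtract averted *cardiorespiratory* deaths from *all-cause* counts,
leaving the non-cardiorespiratory stream untouched; because $e_0$ is
nonlinear in the rates, the loss is computed per posterior draw and then
summarised. Draws in which averted deaths would exceed a cell's
cardiorespiratory count are clipped there and flagged.

The inequality analysis regresses county life-expectancy loss in the
evaluation year on PM2.5 excess over the 2.8 μg/m³ floor plus quintile
indicators of a sociodemographic characteristic (ordinary least squares,
county-count quintiles, ties broken by county id), reporting the Q5-Q1
coefficient with its 95% confidence interval. Population-weighted
variants are available through the `weights` argument.

## Analysis units

Counties whose sex-specific population falls below 25,000 in any year
are recursively merged with neighbours — never across state lines, never
mixing urban and rural counties — until every sex-year population
exceeds the threshold. The published account does not fix a merge order;
the package merges the currently smallest deficient unit into its
smallest eligible neighbour, ties broken by lowest id, which is
deterministic and mimics greedy agglomeration. Deaths and populations
are summed; PM2.5 and covariates are population-weighted, with
log-stored covariates averaged on the natural scale and re-logged.
Counties with no eligible neighbour are flagged and left unmerged.
Percentage covariates are weighted like PM2.5.

## The synthetic generator

`generate_panel()` emulates the 1999-2015 county panel: a rectangular
county grid (rook adjacency) with contiguous state blocks; log-normal
county populations with a fixed national-like age distribution;
declining PM2.5 (population-weighted mean calibrated to 13.6 μg/m³ in
1999 and 8.0 in 2015, spatially correlated, truncated at a 2.8 μg/m³
floor, with the largest declines in the most polluted counties); nine
covariates correlated with PM2.5 at a configurable confounding strength
(realised correlations are calibrated exactly by residualising each
covariate's own spatial field against PM); Poisson cardiorespiratory
deaths from the log-linear model above with known age-sex-specific
$\gamma$ (defaults of the order of published rate ratios: 1.05-1.12 per
10 μg/m³ in mid-adulthood declining to ~1.02 at 85+), plus an
independent non-cardiorespiratory stream whose age profile keeps the
cardiorespiratory share near 40-55% of all deaths; and iid log-rate
overdispersion. All randomness flows from one seed through independent
L'Ecuyer-CMRG streams, one per (county, sex, age), so panels are
bit-reproducible and stable under subsetting.

Two generator choices deserve emphasis:

* **Controlled confounding.** County-level heterogeneity fields are
  orthogonalised (population-weighted) against the county-level design —
  PM levels and county-mean covariates. Independent smooth spatial
  fields have few effective degrees of freedom, so without this step
  chance alignment between the heterogeneity and exposure fields
  contaminates recovery of $\gamma$ by amounts comparable to its
  standard error, identically across all 36 strata. With it, residual
  confounding is governed solely by two explicit dials:
  `confounding_strength` (covariate-PM correlation) and
  `county_confounding` (correlation of county intercepts with PM,
  default 0), the latter used to reproduce the spread of the four
  models under unobserved county-level confounding.
* **Free parameters.** The within-county year-to-year PM variance net of
  trend is not pinned down by published national summaries; it is
  exposed as `pm_year_sd` (default 0.3 μg/m³) rather than silently
  fixed.

What the generator does *not* emulate: exposure measurement error (the
kriged PM2.5 surface's uncertainty), cause-of-death misclassification,
county boundary changes, population migration, and spatially varying
$\gamma$. Passing tests therefore demonstrate the estimator's
correctness under its own assumptions, not robustness to these
real-data complications.

## Numerical choices

* Newton iterations stop on relative objective change below 1e-9 with
  step halving; the linear predictor is clamped at ±40 before
  exponentiation to avoid overflow during line search.
* The hyperparameter search uses Nelder-Mead (golden-section for one
  hyperparameter) on log precisions bounded to [-8, 18], warm-starting
  each inner Newton from the previous mode.
* The Kannisto-Thatcher rescale solves a monotone one-dimensional root
  (tolerance 1e-13) on the log level; the logit-scale fit is exact when
  the data come from a logistic hazard, which is what the 1e-6 recovery
  tolerance in the tests checks.
* Quintile boundaries with tied characteristics are degenerate; the
  assignment falls back to id order and is flagged.

## Problem sizes used in the checks

The suite fits: recovery at 400 counties × 17 years (one stratum);
calibration over 50 replicates of 100 counties (one stratum);
adjustment ordering at 200 counties; an end-to-end null at 400 counties
with large populations (median 800,000), small overdispersion and no
shared county heterogeneity, which gives the Monte-Carlo resolution
needed to bound the null life-expectancy loss at 0.005 years; and 20
end-to-end replicates of 50 counties × 10 years covering all 36 strata,
also without shared heterogeneity (see the independence limitation
below). The acceptance script runs
the full pipeline at 200 counties × 17 years. These sizes are the
package's reduced-scale study conditions; headline magnitudes (for
example national life-expectancy loss of a few tenths of a year under
the floor scenario) match the published order of magnitude, but exact
published totals require the restricted national data.

## Known limitations

* Empirical-Bayes hyperparameters: no propagation of precision
  uncertainty into $\gamma$'s interval (slightly conservative in our
  calibration runs, but not guaranteed to be in all regimes).
* Independent strata: draw-level correlation of $\gamma$ across age-sex
  strata is assumed zero, as implied by fitting strata separately. This
  matters: all 36 strata see the same counties, the same exposure field
  and the same unobserved county heterogeneity, so when such shared
  heterogeneity exists their estimation errors are positively correlated
  (we measure cross-stratum error correlations of 0.3-0.5 on synthetic
  panels with a shared county-intercept field), and a national interval
  built from independent stratum draws understates national uncertainty.
  The package's end-to-end ground-truth checks therefore run on panels
  generated *without* shared heterogeneity, where the independence
  assumption holds exactly; per-stratum intervals are validated
  separately under full heterogeneity. Analyses of real panels should
  read national intervals with this caveat.
* The CAR prior penalises spatially rough county heterogeneity; where
  true heterogeneity is rough and aligned with exposure trends, the
  Bayesian fit (rationally) declines to absorb it and some confounding
  can remain — the restrictive model exists precisely for that case.
* The lifetable treats rates as piecewise-constant within 5-year bands;
  the brute-force single-year oracle bounds the resulting $e_0$ error at
  0.5 years across random hazard schedules.
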