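# pm25life

Direct small-area estimation of the cardiorespiratory mortality burden
and life-expectancy loss attributable to fine particulate matter
(PM2.5), for epidemiologists and environmental-health analysts working
with county-level vital-registration panels.

Rather than transporting hazard ratios from prospective cohorts, the
package estimates the concentration-response directly from county
death-rate panels. For each sex and five-year age group (18 groups,
birth to 85+), deaths follow

    deaths_ct ~ Poisson(rate_ct * population_ct)
    log(rate_ct) = a0 + b0*t + nu_t [+ a_c [+ b_c*t]]
                   + gamma*PM_ct [+ sum_i theta_i * X_ict] + eps_ct

where `nu_t` is a first-order random-walk year effect, `a_c`/`b_c` are
conditional-autoregressive (CAR) county random intercepts/slopes over
the adjacency graph, `eps_ct` is iid overdispersion, and `gamma` is the
log rate ratio per 1 μg/m³ PM2.5. Four nested specifications
(unadjusted; + nine sociodemographic/environmental covariates; + county
intercepts — the main, difference-in-difference-like model; + county
slopes) probe how adjustment changes the estimate. Fitted rate ratios
are converted into averted deaths under counterfactual exposure
scenarios via the exact attributable fraction `D*(1 - exp(gamma*Δ))`,
and into life expectancy through abridged lifetables whose open 85+
group is expanded by the Kannisto–Thatcher method. A quintile
regression quantifies how the loss varies across county sociodemographic
strata at a given PM2.5 level.

Because the underlying vital-registration microdata are restricted, the
package ships a calibrated synthetic county-panel generator
(`generate_panel()`) with known ground-truth parameters — a rectangular
county grid with states and urban/rural classes, declining spatially
correlated PM2.5 (13.6 → 8.0 μg/m³ population-weighted mean over
1999–2015), covariates confounded with PM2.5 at a configurable
strength, and Poisson death counts from the model above — so the whole
pipeline is testable and demonstrable offline.

## Worked example

```r
library(pm25life)

cfg    <- panel_config(n_counties = 100, seed = 42)
panel  <- generate_panel(cfg)
panel
#> County panel: 100 counties, 1999-2015, 2 sexes x 18 age groups (61,200 cells)
#>   population-weighted PM2.5: 13.6 (1999) -> 8.0 (2015) ug/m3
#>   total deaths: 1,394,936 all-cause, 696,200 cardiorespiratory

merged <- merge_small_counties(panel, threshold = 25000)
merged$plan
#> Merge plan: 100 original counties -> 71 units (threshold 25,000)
#>   6 unit(s) flagged unmergeable

fit <- stpois(merged$panel, "covariate_county",
              sex = "female", age_group = "70-74")
fit
#> Spatiotemporal Poisson fit ('covariate_county'), female 70-74
#>   gamma (log RR per ug/m3): 0.00284 (95% CrI -0.01451, 0.02020)
#>   RR per 10 ug/m3: 1.029
```

The printed `gamma` is the posterior mean log rate ratio per 1 μg/m³;
`RR per 10 ug/m3` (here 1.029, i.e. a 2.9% higher death rate per
10 μg/m³) is the conventional reporting unit. The generating value for
this stratum is RR ≈ 1.09 per 10 μg/m³; a single 100-county stratum is
noisy, which is why the pipeline pools all 36 strata:

```r
fits <- fit_strata(merged$panel, "covariate_county")        # 36 strata
att  <- scenario_attribution(merged$panel, fits,
                             scenario_floor(merged$panel, floor = 2.8))
att
#> Attribution under scenario 'floor_2.8' (year 2015, 1000 draws)
#>   female: 112 averted deaths (95% CrI -318, 559) of 14130 observed
#>   male: 105 averted deaths (95% CrI -476, 641) of 19596 observed

le_loss(merged$panel, att, "national")
#> Life-expectancy loss under scenario 'floor_2.8'
#>      unit    sex e0_observed e0_counterfactual loss_mean loss_lo loss_hi
#>  national female     81.0901           81.1157    0.0256 -0.1317   0.191
#>  national   male     77.0948           77.1302    0.0354 -0.0895   0.149
```

Read: had every county's 2015 PM2.5 stood at the lowest observed
concentration (2.8 μg/m³), an estimated 112 female and 105 male
cardiorespiratory deaths would have been averted in 2015 in this
synthetic population, equivalent to about 0.03 years of life expectancy
at birth for either sex. At 100 counties the credible intervals are
wide and include zero — the generating rate ratios here are modest
(1.02–1.12 per 10 μg/m³) and a 71-unit panel carries limited
information; the package's validation suite shows the intervals are
calibrated, and `scripts/acceptance.R` runs the same pipeline at 200
counties where the floor-scenario loss lands at 0.1–0.3 years, the
order of published national estimates.

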