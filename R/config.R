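## Generator configuration: the study conditions for the synthetic county panel.

#' Age groups used throughout the package
#'
#' Eighteen five-year age groups from birth to 85 years and older, the
#' stratification at which every model is fitted and every lifetable built.
#'
#' @return Character vector of 18 age-group labels.
#' @export
age_groups <- function() {
  c(paste(seq(0, 80, 5), seq(4, 84, 5), sep = "-"), "85+")
}

#' Midpoints (in years) of the 18 age groups; 85+ uses the approximate mean
#' age at death within the open interval.
#' @return Numeric vector of length 18.
#' @export
age_midpoints <- function() {
  c(seq(2.5, 82.5, 5), 92.5)
}

## Default age profile of the PM2.5 log rate ratio per ug/m3: rate ratios
## per 10 ug/m3 are largest in middle-aged adults and decline at older ages.
default_rr10 <- function() {
  mid <- age_midpoints()
  rr <- 1.05 + 0.07 * exp(-((mid - 52.5) / 22)^2)
  rr[mid > 80] <- c(1.035, 1.02)
  rr
}

## Default cardiorespiratory share of all-cause mortality by age (rises
## with age; population-weighted total close to one half).
default_cardio_share <- function() {
  mid <- age_midpoints()
  0.15 + 0.45 * stats::plogis((mid - 55) / 15)
}

## Default all-cause baseline death rates (per person-year) by sex and age:
## Gompertz-Makeham shape with a male excess.
default_allcause_rates <- function() {
  mid <- age_midpoints()
  f <- 1.8e-4 + 3.2e-5 * exp(0.092 * mid)
  m <- 3.0e-4 + 4.5e-5 * exp(0.092 * mid)
  rbind(female = f, male = m)
}

## Default covariate effects on the log death rate, in the stored units of
## each covariate (log dollars, percentage points, log rate per 100,000,
## degrees C, percent relative humidity).
default_theta <- function() {
  c(log_income = -0.10, poverty = 0.008, black = 0.002,
    highschool = -0.004, urbanicity_pct = 0.0005, unemployment = 0.010,
    log_lungca = 0.10, temperature = 0.003, humidity = -0.001)
}

#' Names of the nine time-varying county covariates
#'
#' Income and the lung-cancer death-rate proxy for cumulative smoking are
#' stored log-transformed, as flagged by the \code{log_} prefix.
#'
#' @return Character vector of length 9.
#' @export
covariate_names <- function() names(default_theta())

#' Configuration for the synthetic county-panel generator
#'
#' Defines the conditions under which synthetic vital-registration panels
#' are generated: a rectangular county grid with rook adjacency, contiguous
#' state blocks, declining spatially correlated PM2.5 trajectories, nine
#' covariates partially confounded with PM2.5, and Poisson death counts
#' from a log-linear rate model with known (ground-truth) parameters.
#'
#' Defaults emulate the contiguous-US conditions of 1999-2015:
#' population-weighted mean PM2.5 declining from about 13.6 to 8.0 ug/m3,
#' a 2.8 ug/m3 observed floor, rate ratios per 10 ug/m3 of roughly
#' 1.02-1.12 across ages, and a cardiorespiratory share of roughly 40-55%
#' of all deaths.
#'
#' @param n_counties Number of counties, laid out on a rectangular grid.
#' @param n_states Number of states (contiguous rectangular blocks).
#' @param years Inclusive integer range of calendar years.
#' @param true_gamma Matrix (2 x 18, rows female/male) of log rate ratios
#'   per ug/m3 PM2.5, or a single number recycled to all strata.
#' @param true_theta Named 9-vector of covariate effects on the log rate.
#' @param baseline_log_rates Matrix (2 x 18) of baseline log
#'   cardiorespiratory death rates at reference covariate/PM levels.
#' @param pm_start_mean,pm_end_mean Mean PM2.5 (ug/m3) in the first and
#'   last year.
#' @param pm_spatial_sd Between-county SD of the PM2.5 spatial field.
#' @param pm_year_sd SD of iid year-to-year PM2.5 noise around the county
#'   trend (not pinned down by national data; free parameter).
#' @param pm_floor Lower truncation for PM2.5 (ug/m3).
#' @param confounding_strength Correlation between PM2.5 and each
#'   covariate's latent component (sign per covariate via
#'   \code{covariate_signs}).
#' @param covariate_signs Named 9-vector of +/-1 giving the direction of
#'   each covariate's correlation with PM2.5.
#' @param overdispersion_sd SD of iid log-rate noise per county-year cell.
#' @param county_intercept_sd SD of the spatially correlated county
#'   intercept field (0 disables county heterogeneity).
#' @param county_confounding Correlation between the county intercept
#'   field and the county's PM2.5 level. At the default 0 the county
#'   heterogeneity is generated orthogonal (in sample) to the exposure
#'   field, so residual confounding is governed solely by
#'   \code{confounding_strength}; positive values create unobserved
#'   county-level confounding that only the county-intercept models can
#'   remove.
#' @param county_slope_sd SD of county-specific linear log-rate trends.
#' @param trend_per_year Common log-rate trend per year.
#' @param noncardio_fraction Length-18 vector: fraction of all-cause deaths
#'   that are non-cardiorespiratory, by age.
#' @param pop_meanlog,pop_sdlog Log-normal parameters of county total
#'   population.
#' @param spatial_range Correlation range of spatial fields, in grid cells.
#' @param seed Integer seed; all randomness flows from it through
#'   per-(county, sex, age) streams.
#'
#' @return An object of class \code{panel_config}.
#' @examples
#' cfg <- panel_config(n_counties = 20, seed = 1)
#' cfg$grid
#' @export
panel_config <- function(n_counties = 400,
                         n_states = 9,
                         years = 1999:2015,
                         true_gamma = NULL,
                         true_theta = default_theta(),
                         baseline_log_rates = NULL,
                         pm_start_mean = 13.6,
                         pm_end_mean = 8.0,
                         pm_spatial_sd = 2.5,
                         pm_year_sd = 0.3,
                         pm_floor = 2.8,
                         confounding_strength = 0.3,
                         covariate_signs = c(log_income = -1, poverty = 1,
                                             black = 1, highschool = -1,
                                             urbanicity_pct = 1,
                                             unemployment = 1, log_lungca = 1,
                                             temperature = 1, humidity = -1),
                         overdispersion_sd = 0.05,
                         county_intercept_sd = 0.10,
                         county_confounding = 0,
                         county_slope_sd = 0,
                         trend_per_year = -0.015,
                         noncardio_fraction = 1 - default_cardio_share(),
                         pop_meanlog = log(6e4),
                         pop_sdlog = 0.8,
                         spatial_range = 3,
                         seed = 1L) {
  stopifnot(n_counties >= 1, n_states >= 1, length(years) >= 2,
            pm_floor >= 0, pm_spatial_sd >= 0, pm_year_sd >= 0,
            overdispersion_sd >= 0, county_intercept_sd >= 0,
            county_slope_sd >= 0, is.numeric(seed), length(seed) == 1)
  years <- as.integer(years)
  if (any(diff(years) != 1L)) stop("`years` must be consecutive")
  ages <- age_groups()
  if (is.null(true_gamma)) true_gamma <- log(default_rr10()) / 10
  if (length(true_gamma) == 1)
    true_gamma <- matrix(true_gamma, 2, 18)
  else if (is.null(dim(true_gamma)))
    true_gamma <- rbind(true_gamma, true_gamma)
  true_gamma <- matrix(as.numeric(true_gamma), 2, 18,
                       dimnames = list(c("female", "male"), ages))
  if (length(noncardio_fraction) != 18 ||
      any(noncardio_fraction <= 0) || any(noncardio_fraction >= 1))
    stop("`noncardio_fraction` must be 18 fractions strictly in (0, 1)")
  if (is.null(baseline_log_rates)) {
    share <- 1 - noncardio_fraction
    baseline_log_rates <- log(default_allcause_rates() *
                                rbind(share, share))
  }
  baseline_log_rates <- matrix(as.numeric(baseline_log_rates), 2, 18,
                               dimnames = list(c("female", "male"), ages))
  if (length(true_theta) != 9 || is.null(names(true_theta)) ||
      !all(names(true_theta) == covariate_names()))
    stop("`true_theta` must be a named 9-vector in covariate_names() order")
  if (abs(confounding_strength) > 0.95)
    stop("`confounding_strength` must lie in [-0.95, 0.95]")
  if (abs(county_confounding) > 0.95)
    stop("`county_confounding` must lie in [-0.95, 0.95]")

  ## rectangular grid: largest factor pair at or below sqrt(n)
  nr <- floor(sqrt(n_counties))
  while (n_counties %% nr != 0) nr <- nr - 1
  nc <- n_counties %/% nr
  if (nr * nc != n_counties)
    stop("inconsistent grid: cannot factor n_counties into a rectangle")

  structure(list(
    n_counties = as.integer(n_counties), n_states = as.integer(n_states),
    years = years, age_groups = ages,
    true_gamma = true_gamma, true_theta = true_theta,
    baseline_log_rates = baseline_log_rates,
    pm_start_mean = pm_start_mean, pm_end_mean = pm_end_mean,
    pm_spatial_sd = pm_spatial_sd, pm_year_sd = pm_year_sd,
    pm_floor = pm_floor,
    confounding_strength = confounding_strength,
    covariate_signs = covariate_signs,
    overdispersion_sd = overdispersion_sd,
    county_intercept_sd = county_intercept_sd,
    county_confounding = county_confounding,
    county_slope_sd = county_slope_sd,
    trend_per_year = trend_per_year,
    noncardio_fraction = noncardio_fraction,
    pop_meanlog = pop_meanlog, pop_sdlog = pop_sdlog,
    spatial_range = spatial_range,
    grid = c(nrow = nr, ncol = nc),
    seed = as.integer(seed)), class = "panel_config")
}

#' @export
print.panel_config <- function(x, ...) {
  cat("Synthetic county-panel configuration\n")
  cat(sprintf("  counties: %d (%d x %d grid), states: %d\n",
              x$n_counties, x$grid["nrow"], x$grid["ncol"], x$n_states))
  cat(sprintf("  years: %d-%d, age groups: %d, seed: %d\n",
              min(x$years), max(x$years), length(x$age_groups), x$seed))
  cat(sprintf("  PM2.5: %.1f -> %.1f ug/m3 (spatial sd %.1f, floor %.1f)\n",
              x$pm_start_mean, x$pm_end_mean, x$pm_spatial_sd, x$pm_floor))
  cat(sprintf("  confounding: %.2f, overdispersion sd: %.3f\n",
              x$confounding_strength, x$overdispersion_sd))
  invisible(x)
}

#' Read a generator configuration from a YAML file
#'
#' Accepts a declarative key-value file whose entries are
#' \code{panel_config()} arguments.
#'
#' @param path Path to a YAML file.
#' @return A \code{panel_config} object.
#' @export
panel_config_from_yaml <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required to read configuration files")
  args <- yaml::read_yaml(path)
  if (!is.null(args$years) && length(args$years) == 2)
    args$years <- args$years[1]:args$years[2]
  for (nm in c("true_theta", "covariate_signs"))
    if (!is.null(args[[nm]])) args[[nm]] <- unlist(args[[nm]])
  do.call(panel_config, args)
}
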