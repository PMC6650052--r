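## Counterfactual attribution: averted cardiorespiratory deaths under
## alternative PM2.5 scenarios.

#' Averted deaths under a counterfactual exposure (closed form)
#'
#' Under the log-linear rate model, moving exposure from \code{pm_obs} to
#' \code{pm_cf} changes expected deaths by the factor
#' \code{exp(gamma * (pm_cf - pm_obs))}; the averted count is
#' \code{observed * (1 - exp(gamma * (pm_cf - pm_obs)))}. Positive when
#' \code{gamma > 0} and the counterfactual is cleaner; negative values
#' represent excess deaths under a dirtier scenario.
#'
#' @param observed Observed death count(s).
#' @param pm_obs Observed PM2.5 (ug/m3).
#' @param pm_cf Counterfactual PM2.5 (ug/m3).
#' @param gamma Log rate ratio per ug/m3.
#' @return Averted deaths (same length as the longest argument).
#' @examples
#' averted_deaths(1000, 12.8, 2.8, log(1.1) / 10)  # ~90.9
#' @export
averted_deaths <- function(observed, pm_obs, pm_cf, gamma) {
  stopifnot(all(observed >= 0))
  observed * (1 - exp(gamma * (pm_cf - pm_obs)))
}

#' Lowest county PM2.5 concentration in a year
#'
#' @param panel A \code{county_panel}.
#' @param year Evaluation year (default: last panel year).
#' @return Minimum county PM2.5 (ug/m3).
#' @export
county_floor <- function(panel, year = max(panel$years)) {
  stopifnot(inherits(panel, "county_panel"))
  min(panel$exposure$pm[panel$exposure$year == year])
}

#' Counterfactual PM2.5 scenarios
#'
#' \code{scenario_floor()} sets every county's PM2.5 to a common floor
#' (default 2.8 ug/m3, the lowest concentration observed in US counties)
#' in the evaluation year. \code{scenario_reduction()} evaluates the
#' benefit of achieved reductions: deaths in \code{from_year} are compared
#' with those expected had each county already been at its
#' \code{to_year} concentration.
#'
#' @param panel A \code{county_panel}.
#' @param floor Floor concentration (ug/m3).
#' @param year,from_year,to_year Evaluation/reference years.
#' @return An object of class \code{pm_scenario}: \code{name},
#'   \code{years} (evaluation years) and \code{pm_cf}, a vector of
#'   counterfactual concentrations named by county id.
#' @export
scenario_floor <- function(panel, floor = 2.8, year = max(panel$years)) {
  stopifnot(floor >= 0)
  ids <- panel$counties$county
  structure(list(name = sprintf("floor_%.1f", floor), years = year,
                 pm_cf = stats::setNames(rep(floor, length(ids)),
                                         as.character(ids))),
            class = "pm_scenario")
}

#' @rdname scenario_floor
#' @export
scenario_reduction <- function(panel, from_year = min(panel$years),
                               to_year = max(panel$years)) {
  ex <- panel$exposure[panel$exposure$year == to_year, ]
  structure(list(name = sprintf("reduction_%d_to_%d", from_year, to_year),
                 years = from_year,
                 pm_cf = stats::setNames(ex$pm, as.character(ex$county))),
            class = "pm_scenario")
}

#' Attribute deaths to PM2.5 under a counterfactual scenario
#'
#' Applies \code{averted_deaths()} cell-wise for every county, sex and
#' age group in the evaluation year(s), per posterior draw of each
#' stratum's PM2.5 coefficient (strata are fitted independently, so their
#' draws are independent), and aggregates draw-by-draw to county and
#' national totals. Interval endpoints are percentiles of the draw-level
#' totals.
#'
#' @param panel A \code{county_panel}.
#' @param fits A \code{stpois_strata} list covering all 36 sex-age strata
#'   (or all strata present in the panel).
#' @param scenario A \code{pm_scenario}.
#' @return An object of class \code{pm_attribution} with elements
#'   \code{cell} (county-year-sex-age means and 95% intervals),
#'   \code{county}, \code{national} and draw-level arrays
#'   \code{draws[[sex]]} (county x age x draw) used by \code{le_loss()}.
#' @export
scenario_attribution <- function(panel, fits, scenario) {
  stopifnot(inherits(panel, "county_panel"),
            inherits(scenario, "pm_scenario"))
  sexes <- c("female", "male")
  need <- as.vector(outer(sexes, age_groups(), paste, sep = "."))
  miss <- setdiff(need, names(fits))
  if (length(miss))
    stop("missing stratum fits: ", paste(miss, collapse = ", "))
  R <- length(fits[[need[1]]]$gamma_draws)
  ids <- sort(panel$counties$county)
  C <- length(ids)
  ev <- panel$events
  ex <- panel$exposure
  yr <- scenario$years
  cells <- NULL
  draws <- list()
  national <- list()
  for (s in sexes) {
    arr <- array(0, c(C, 18, R),
                 dimnames = list(as.character(ids), age_groups(), NULL))
    obs_mat <- matrix(0, C, 18, dimnames = dimnames(arr)[1:2])
    for (a_i in seq_len(18)) {
      a <- age_groups()[a_i]
      gam <- fits[[paste(s, a, sep = ".")]]$gamma_draws
      for (y in yr) {
        sel <- ev$sex == s & ev$age == a & ev$year == y
        sub <- ev[sel, ]
        at <- match(sub$county, ids)
        pm_obs <- ex$pm[match(paste(sub$county, y),
                              paste(ex$county, ex$year))]
        pm_cf <- scenario$pm_cf[as.character(sub$county)]
        delta <- pm_cf - pm_obs
        ## counties x draws: D * (1 - exp(gamma_r * delta_c))
        fac <- 1 - exp(outer(delta, gam))
        arr[at, a_i, ] <- arr[at, a_i, ] + sub$cardio_deaths * fac
        obs_mat[at, a_i] <- obs_mat[at, a_i] + sub$cardio_deaths
      }
    }
    draws[[s]] <- arr
    nat_draws <- apply(arr, 3, sum)
    national[[s]] <- c(mean = mean(nat_draws),
                       stats::quantile(nat_draws, c(0.025, 0.975)),
                       observed = sum(obs_mat))
    cty <- apply(arr, c(1, 3), sum)
    cells_s <- data.frame(
      county = rep(ids, 18), sex = s,
      age = rep(age_groups(), each = C),
      observed = as.vector(obs_mat),
      averted_mean = as.vector(apply(arr, c(1, 2), mean)),
      averted_lo = as.vector(apply(arr, c(1, 2),
                                   stats::quantile, 0.025)),
      averted_hi = as.vector(apply(arr, c(1, 2),
                                   stats::quantile, 0.975)))
    cells <- rbind(cells, cells_s)
  }
  county_tab <- do.call(rbind, lapply(sexes, function(s) {
    cty <- apply(draws[[s]], c(1, 3), sum)
    data.frame(county = ids, sex = s,
               averted_mean = rowMeans(cty),
               averted_lo = apply(cty, 1, stats::quantile, 0.025),
               averted_hi = apply(cty, 1, stats::quantile, 0.975))
  }))
  structure(list(scenario = scenario, years = yr, cell = cells,
                 county = county_tab,
                 national = do.call(rbind, national),
                 draws = draws, n_draws = R),
            class = "pm_attribution")
}

#' @export
print.pm_attribution <- function(x, ...) {
  cat(sprintf("Attribution under scenario '%s' (year %s, %d draws)\n",
              x$scenario$name, paste(x$years, collapse = ","), x$n_draws))
  nat <- x$national
  for (s in rownames(nat))
    cat(sprintf("  %s: %.0f averted deaths (95%% CrI %.0f, %.0f) of %.0f observed\n",
                s, nat[s, "mean"], nat[s, "2.5%"], nat[s, "97.5%"],
                nat[s, "observed"]))
  invisible(x)
}
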