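## Independent oracles and hand-built fixtures used across the suite.

## Brute-force single-year lifetable under piecewise-constant hazards:
## takes the full extended rate schedule (5-year bands plus open final
## interval) and integrates survival year by year with exponential
## within-band survival. Independent of the package's abridged algebra.
brute_force_e0 <- function(rates, band_lo) {
  k <- length(rates)
  e0 <- 0
  l <- 1
  for (i in seq_len(k - 1)) {
    m <- rates[i]
    width <- band_lo[i + 1] - band_lo[i]
    for (yr in seq_len(width)) {
      if (m <= 0) { e0 <- e0 + l; next }
      l_next <- l * exp(-m)
      e0 <- e0 + (l - l_next) / m
      l <- l_next
    }
  }
  m <- rates[k]
  if (m > 0) e0 <- e0 + l / m
  e0
}

## Stationary-population remaining life expectancy over an extension
## schedule (five 5-year bands + open interval), used to construct
## consistent open-interval rates when testing the Kannisto-Thatcher fit.
ext_e85_oracle <- function(rates) {
  l <- 1; e <- 0
  for (j in 1:(length(rates) - 1)) {
    m <- rates[j]
    l_next <- l * exp(-5 * m)
    e <- e + l * (1 - exp(-5 * m)) / m
    l <- l_next
  }
  e + l / rates[length(rates)]
}

## Hand-built county panel: populations per county (split evenly over
## sex-age cells), constant covariates, explicit adjacency, state and
## urbanicity. Deaths are deterministic unless pois_seed is given.
make_toy_panel <- function(pops, pm, years = 2014:2015,
                           state = rep(1, length(pops)),
                           urbanicity = rep("urban", length(pops)),
                           edges = NULL, cardio_rate = 0.004,
                           allcause_rate = 0.01, pois_seed = NULL) {
  C <- length(pops)
  counties <- data.frame(county = seq_len(C), state = state,
                         urbanicity = urbanicity)
  if (is.null(edges)) edges <- data.frame(from = numeric(0), to = numeric(0))
  Tn <- length(years)
  ex <- expand.grid(county = seq_len(C), year = years)
  ex$pm <- rep(pm, Tn)
  for (nm in covariate_names()) ex[[nm]] <- 1
  evg <- expand.grid(county = seq_len(C), year = years,
                     sex = c("female", "male"), age = age_groups(),
                     stringsAsFactors = FALSE)
  evg$population <- pmax(1, round(rep(pops, length.out = nrow(evg)) / 18))
  if (!is.null(pois_seed)) {
    set.seed(pois_seed)
    evg$cardio_deaths <- rpois(nrow(evg), evg$population * cardio_rate)
    evg$allcause_deaths <- evg$cardio_deaths +
      rpois(nrow(evg), evg$population * (allcause_rate - cardio_rate))
  } else {
    evg$cardio_deaths <- round(evg$population * cardio_rate)
    evg$allcause_deaths <- round(evg$population * allcause_rate)
  }
  county_panel(counties, edges, ex, evg)
}

## Minimal stand-ins for fitted strata with a known constant PM2.5
## coefficient: scenario_attribution() only touches $gamma_draws.
make_const_fits <- function(gamma, n_draws = 50) {
  fits <- list()
  for (s in c("female", "male")) for (a in age_groups())
    fits[[paste(s, a, sep = ".")]] <-
      structure(list(gamma_draws = rep(gamma, n_draws)), class = "stpois")
  structure(fits, class = "stpois_strata")
}

## Small default generator config for fast model tests.
small_config <- function(...) {
  args <- list(...)
  defaults <- list(n_counties = 50, years = 2006:2015, seed = 1)
  do.call(panel_config, utils::modifyList(defaults, args))
}
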