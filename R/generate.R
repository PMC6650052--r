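## Synthetic county-panel generator with known ground truth.

## Deterministic derived seeds (for per-stratum inference draw seeds):
## mixes (seed, county, sex, age) with distinct Mersenne-prime
## multipliers, exact in double arithmetic, result < 2^31.
stream_seed <- function(seed, county, sex, age) {
  h <- (abs(seed) * 1000003 + county * 8191 + sex * 131071 +
          age * 524287) %% 2147483647
  as.integer((h * 48271) %% 2147483647)
}

## Table of independent L'Ecuyer-CMRG stream states, all derived from one
## seed; used so every (county, sex, age) cell of the generator has its
## own statistically independent stream.
make_streams <- function(seed, n) {
  kind <- RNGkind()
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    RNGkind(kind[1], kind[2], kind[3])
    if (had) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed, kind = "L'Ecuyer-CMRG")
  states <- vector("list", n)
  s <- get(".Random.seed", envir = globalenv())
  for (i in seq_len(n)) {
    states[[i]] <- s
    s <- parallel::nextRNGStream(s)
  }
  states
}

## Evaluate a function under a local RNG stream, restoring global state.
with_stream <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(expr)
}

## Mean-zero, unit-variance Gaussian field on an nr x nc grid with
## exponential correlation over grid distance.
grid_field <- function(nr, nc, range) {
  xy <- cbind(rep(seq_len(nr), nc), rep(seq_len(nc), each = nr))
  d <- as.matrix(stats::dist(xy))
  S <- exp(-d / range) + diag(1e-8, nrow(d))
  z <- drop(t(chol(S)) %*% stats::rnorm(nrow(d)))
  (z - mean(z)) / max(stats::sd(z), 1e-12)
}

## Fixed national-like age distribution over the 18 age groups.
age_distribution <- function() {
  p <- c(6.2, 6.5, 6.7, 6.8, 6.6, 6.7, 6.5, 6.3, 6.4, 6.7,
         7.0, 6.5, 5.7, 4.7, 3.7, 2.8, 2.0, 1.9)
  p / sum(p)
}

#' Generate a synthetic county panel
#'
#' Lays counties on a rectangular grid (rook adjacency, contiguous state
#' blocks), draws county populations and a declining, spatially correlated
#' PM2.5 surface truncated at the configured floor, constructs nine
#' covariates correlated with PM2.5 at the configured confounding
#' strength, and draws cardiorespiratory death counts from a Poisson
#' log-linear model with the configured ground-truth parameters (plus an
#' independent non-cardiorespiratory death stream so all-cause lifetables
#' are computable). All randomness flows from \code{config$seed} through
#' one stream per (county, sex, age), so identical configurations give
#' bit-identical panels.
#'
#' @param config A \code{panel_config}.
#' @return A \code{county_panel} carrying the config.
#' @examples
#' panel <- generate_panel(panel_config(n_counties = 20, seed = 7))
#' panel
#' @export
generate_panel <- function(config) {
  if (!inherits(config, "panel_config"))
    stop("configuration error: `config` must be a panel_config")
  nr <- config$grid[["nrow"]]; nc <- config$grid[["ncol"]]
  C <- config$n_counties
  if (nr * nc != C) stop("configuration error: inconsistent grid")
  years <- config$years; Tn <- length(years)
  ages <- config$age_groups

  row_i <- rep(seq_len(nr), nc); col_i <- rep(seq_len(nc), each = nr)

  ## states: contiguous blocks of grid cells
  sr <- max(1, floor(sqrt(config$n_states)))
  while (config$n_states %% sr != 0) sr <- sr - 1
  sc <- config$n_states %/% sr
  state <- (pmin(sr - 1, (row_i - 1) %/% max(1, ceiling(nr / sr)))) * sc +
    pmin(sc - 1, (col_i - 1) %/% max(1, ceiling(nc / sc))) + 1L

  ## rook adjacency on the grid
  idx <- matrix(seq_len(C), nr, nc)
  edges <- rbind(
    if (nr > 1) cbind(as.vector(idx[-nr, ]), as.vector(idx[-1, ])),
    if (nc > 1) cbind(as.vector(idx[, -nc]), as.vector(idx[, -1])))
  adjacency <- data.frame(from = edges[, 1], to = edges[, 2])

  ## one independent RNG stream per panel-level field set and per
  ## (county, sex, age) cell; global RNG state restored on exit
  states <- make_streams(config$seed, 3 + C * 36)
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old_seed <- get(".Random.seed", envir = globalenv())
  old_kind <- RNGkind()
  on.exit({
    RNGkind(old_kind[1], old_kind[2], old_kind[3])
    if (had_seed) assign(".Random.seed", old_seed, envir = globalenv())
  })
  use_stream <- function(i) assign(".Random.seed", states[[i]],
                                   envir = globalenv())

  use_stream(1)
  fields <- list(pm = grid_field(nr, nc, config$spatial_range),
                 pm2 = grid_field(nr, nc, config$spatial_range),
                 county = grid_field(nr, nc, config$spatial_range),
                 slope = grid_field(nr, nc, config$spatial_range),
                 cov = replicate(9, {
                   f <- grid_field(nr, nc, config$spatial_range)
                   e <- stats::rnorm(C * Tn, sd = 0.5)
                   (rep(f, Tn) + e) / sqrt(1.25)
                 }))
  use_stream(2)
  pop_total <- pmax(1000, round(stats::rlnorm(C, config$pop_meanlog,
                                              config$pop_sdlog)))
  urbanicity <- ifelse(pop_total > stats::quantile(pop_total, 0.6),
                       "urban", "rural")

  ## PM2.5 trajectories: county start level from a spatial field, linear
  ## decline to a compressed end level (largest declines where most
  ## polluted), iid year noise, truncated at the floor
  pm_start <- config$pm_start_mean + config$pm_spatial_sd * fields$pm
  pm_end <- config$pm_end_mean +
    0.35 * config$pm_spatial_sd * fields$pm +
    0.32 * config$pm_spatial_sd * fields$pm2
  frac <- (rep(years, each = C) - years[1]) / (Tn - 1)
  use_stream(3)
  pm_noise <- stats::rnorm(C * Tn, sd = config$pm_year_sd)
  pm <- pmax(config$pm_floor,
             rep(pm_start, Tn) * (1 - frac) + rep(pm_end, Tn) * frac +
               pm_noise)

  ## covariates: latent = rho * standardised PM + sqrt(1-rho^2) * own field
  rho <- config$confounding_strength
  pm_sd <- stats::sd(pm)
  ## a flat PM field (degenerate, but valid generator input) cannot
  ## confound anything
  pm_z <- if (pm_sd < 1e-12) rep(0, length(pm)) else (pm - mean(pm)) / pm_sd
  loc <- c(log_income = log(24000), poverty = 12, black = 10,
           highschool = 80, urbanicity_pct = 55, unemployment = 4.5,
           log_lungca = log(45), temperature = 13, humidity = 69)
  scl <- c(log_income = 0.25, poverty = 4, black = 6, highschool = 6,
           urbanicity_pct = 20, unemployment = 1.5, log_lungca = 0.3,
           temperature = 4, humidity = 5)
  X <- matrix(0, C * Tn, 9, dimnames = list(NULL, covariate_names()))
  for (j in 1:9) {
    nm <- covariate_names()[j]
    ## residualise the covariate's own field against PM so the realised
    ## correlation equals the configured confounding strength (spatially
    ## correlated fields otherwise have too few effective degrees of
    ## freedom for the sample correlation to land near its target)
    u <- fields$cov[, j]
    if (pm_sd >= 1e-12) u <- u - (sum(u * pm_z) / sum(pm_z^2)) * pm_z
    u <- (u - mean(u)) / stats::sd(u)
    z <- config$covariate_signs[[nm]] *
      (rho * pm_z + sqrt(1 - rho^2) * u)
    x <- loc[[nm]] + scl[[nm]] * z
    if (nm %in% c("poverty", "black", "highschool", "urbanicity_pct",
                  "unemployment"))
      x <- pmin(100, pmax(0.1, x))
    X[, j] <- x
  }

  exposure <- data.frame(county = rep(seq_len(C), Tn),
                         year = rep(years, each = C),
                         pm = pm, X, check.names = FALSE)

  ## ground-truth latent structure for the log rate. County heterogeneity
  ## is orthogonalised (in sample) against the county PM level so that
  ## confounding is controlled explicitly: `county_confounding` sets the
  ## correlation between county intercepts and PM, and at 0 recovery of
  ## gamma is a sharp test not contaminated by chance alignment of the
  ## two spatial fields.
  pm_county <- (pm_start + pm_end) / 2
  pm_county_z <- (pm_county - mean(pm_county)) /
    max(stats::sd(pm_county), 1e-12)
  ## county-level design the heterogeneity must not align with: PM levels
  ## and county-mean covariates, population-weighted as the Poisson
  ## likelihood effectively weights counties
  Xbar <- apply(X, 2, function(v) rowsum(v, exposure$county)[, 1] / Tn)
  G <- cbind(1, pm_start, pm_end, if (C > ncol(Xbar) + 4) Xbar)
  orth <- function(f) {
    r <- stats::lm.wfit(G, f, w = pop_total)$residuals
    (r - mean(r)) / max(stats::sd(r), 1e-12)
  }
  cc <- config$county_confounding
  alpha_c <- config$county_intercept_sd *
    (cc * pm_county_z + sqrt(1 - cc^2) * orth(fields$county))
  beta_c <- config$county_slope_sd * orth(fields$slope)
  t_c <- rep(years, each = C) - mean(years)
  pm_ref <- mean(pm)
  x_dev <- sweep(X, 2, loc)   # covariate deviations from reference levels
  theta_part <- drop(x_dev %*% config$true_theta)

  ## per (county, sex, age) death streams
  age_p <- age_distribution()
  sexes <- c("female", "male")
  n_cell <- C * Tn * 2 * 18
  ev_county <- integer(n_cell); ev_year <- integer(n_cell)
  ev_sex <- character(n_cell); ev_age <- character(n_cell)
  ev_pop <- numeric(n_cell); ev_cardio <- numeric(n_cell)
  ev_all <- numeric(n_cell)
  lambda_cardio <- numeric(n_cell)
  row0 <- 0L
  base_common <- rep(alpha_c, Tn) + rep(beta_c, Tn) * t_c +
    config$trend_per_year * t_c + theta_part
  for (s in 1:2) for (a in 1:18) {
    gam <- config$true_gamma[s, a]
    lograte0 <- config$baseline_log_rates[s, a] +
      base_common + gam * (pm - pm_ref)
    frac_nc <- config$noncardio_fraction[a]
    m_nc <- exp(config$baseline_log_rates[s, a]) * frac_nc / (1 - frac_nc)
    for (ci in seq_len(C)) {
      pop <- max(1, round(pop_total[ci] * 0.5 * age_p[a]))
      rows <- ci + C * (seq_len(Tn) - 1)        # county ci, all years
      use_stream(3L + (ci - 1L) * 36L + (s - 1L) * 18L + a)
      eps <- stats::rnorm(Tn, sd = config$overdispersion_sd)
      lam <- pop * exp(lograte0[rows] + eps)
      draws <- list(lam = lam,
                    card = stats::rpois(Tn, lam),
                    nonc = stats::rpois(Tn, pop * m_nc *
                                          exp(config$trend_per_year *
                                                (years - mean(years)))))
      allc <- pmin(draws$card + draws$nonc, pop)
      card <- pmin(draws$card, allc)
      at <- row0 + seq_len(Tn)
      ev_county[at] <- ci; ev_year[at] <- years
      ev_sex[at] <- sexes[s]; ev_age[at] <- ages[a]
      ev_pop[at] <- pop; ev_cardio[at] <- card; ev_all[at] <- allc
      lambda_cardio[at] <- draws$lam
      row0 <- row0 + Tn
    }
  }
  events <- data.frame(county = ev_county, year = ev_year, sex = ev_sex,
                       age = ev_age, population = ev_pop,
                       cardio_deaths = ev_cardio, allcause_deaths = ev_all)
  counties <- data.frame(county = seq_len(C), state = state,
                         urbanicity = urbanicity,
                         grid_row = row_i, grid_col = col_i)
  panel <- county_panel(counties, adjacency, exposure, events,
                        config = config)
  attr(panel, "latent") <- list(alpha_county = alpha_c, beta_county = beta_c,
                                pm_ref = pm_ref,
                                lambda_cardio = lambda_cardio)
  panel
}

#' Ground-truth record for a generated panel
#'
#' Returns the generating parameters and the exact expected averted deaths
#' under any counterfactual PM2.5 scenario, computed from the generating
#' Poisson means (not the realised counts), for parameter-recovery and
#' end-to-end tests.
#'
#' @param config The \code{panel_config} the panel was generated from.
#' @param panel The \code{county_panel} produced by
#'   \code{generate_panel(config)}.
#' @return A list with elements \code{gamma} (2 x 18 matrix),
#'   \code{theta}, \code{alpha_county}, \code{beta_county},
#'   \code{lambda_cardio} (expected cardiorespiratory deaths per events
#'   row) and the function \code{expected_averted(scenario)} returning the
#'   exact expected national averted deaths per sex.
#' @export
generate_truth_record <- function(config, panel) {
  if (!inherits(panel, "county_panel") || is.null(panel$config) ||
      !identical(panel$config$seed, config$seed) ||
      !identical(panel$config$true_gamma, config$true_gamma) ||
      !identical(panel$config$years, config$years) ||
      !identical(panel$config$n_counties, config$n_counties))
    stop("mismatched config/panel: panel was not generated from this config")
  latent <- attr(panel, "latent")
  if (is.null(latent)) stop("panel carries no generator latent record")
  ev <- panel$events
  gamma_cell <- config$true_gamma[cbind(
    match(ev$sex, c("female", "male")), match(ev$age, config$age_groups))]
  pm_map <- panel$exposure$pm
  names(pm_map) <- paste(panel$exposure$county, panel$exposure$year)
  pm_cell <- as.numeric(pm_map[paste(ev$county, ev$year)])

  expected_averted <- function(scenario) {
    stopifnot(inherits(scenario, "pm_scenario"))
    out <- c(female = 0, male = 0)
    for (yr in scenario$years) {
      in_y <- ev$year == yr
      cf <- scenario$pm_cf[as.character(ev$county[in_y])]
      av <- latent$lambda_cardio[in_y] *
        (1 - exp(gamma_cell[in_y] * (cf - pm_cell[in_y])))
      out <- out + as.numeric(tapply(av, ev$sex[in_y],
                                     sum)[c("female", "male")])
    }
    out
  }

  list(gamma = config$true_gamma, theta = config$true_theta,
       alpha_county = latent$alpha_county,
       beta_county = latent$beta_county,
       lambda_cardio = latent$lambda_cardio,
       pm_ref = latent$pm_ref,
       expected_averted = expected_averted)
}
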