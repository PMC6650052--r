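test_that("build_design centres the year and honours the model flags", {
  p <- generate_panel(panel_config(n_counties = 20, years = 1999:2015,
                                   seed = 1))
  d <- build_design(p, "covariate", sex = "female", age_group = "60-64")
  expect_equal(range(d$t), c(-8, 8))
  expect_equal(ncol(d$X), 9)
  d0 <- build_design(p, "unadjusted", sex = "male", age_group = "85+")
  expect_null(d0$X)
  expect_equal(length(d0$y), 20 * 17)
  ## the four specs have the documented flag patterns
  flags <- t(sapply(c("unadjusted", "covariate", "covariate_county",
                      "restrictive"), function(nm) {
    s <- model_spec(nm)
    c(s$include_covariates, s$include_county_intercepts,
      s$include_county_slopes)
  }))
  expect_equal(unname(flags),
               matrix(c(F, F, F, T, F, F, T, T, F, T, T, T), 4, 3,
                      byrow = TRUE))
})

test_that("a PM field with no variation is a degenerate design", {
  cfg <- small_config(n_counties = 20, pm_start_mean = 8,
                      pm_end_mean = 8, pm_spatial_sd = 0, pm_year_sd = 0,
                      pm_floor = 0)
  p <- generate_panel(cfg)
  expect_error(stpois(p, "unadjusted", sex = "female",
                      age_group = "75-79"), "degenerate")
})

test_that("fixed-effects-only posterior means agree with the ML Poisson oracle", {
  p <- generate_panel(small_config(n_counties = 25, seed = 4))
  ctl <- stpois_control(rw1 = FALSE, overdispersion = FALSE)
  for (model in c("unadjusted", "covariate")) {
    f <- stpois(p, model, sex = "female", age_group = "75-79",
                control = ctl)
    d <- build_design(p, model, sex = "female", age_group = "75-79")
    df <- data.frame(y = d$y, t = d$t, pm = d$pm)
    form <- y ~ t + pm
    if (!is.null(d$X)) {
      df <- cbind(df, scale(d$X, scale = FALSE))
      form <- reformulate(c("t", "pm", covariate_names()), "y")
    }
    g <- glm(form, family = poisson, offset = log(d$population), data = df)
    sds <- sqrt(diag(vcov(f)))
    expect_true(all(abs(coef(f)[-1] - coef(g)[-1]) < 3 * sds[-1]))
    ## with a weak prior the agreement is in fact much tighter
    expect_lt(abs(coef(f)[["gamma"]] - coef(g)[["pm"]]),
              0.05 * abs(coef(g)[["pm"]]) + 1e-4)
  }
})

test_that("the PM coefficient is recovered from a known generating model", {
  tg <- log(1.25) / 10
  p <- generate_panel(small_config(n_counties = 50, seed = 1,
                                   true_gamma = tg))
  f <- stpois(p, "covariate_county", sex = "female", age_group = "70-74")
  expect_true(f$converged)
  z <- (coef(f)[["gamma"]] - tg) / sqrt(vcov(f)["gamma", "gamma"])
  expect_lt(abs(z), 3)
  ## identifiability constraints hold: CAR field and RW1 sum to zero
  expect_lt(abs(sum(f$alpha_county$mean)), 1e-6)
  expect_lt(abs(sum(f$nu$mean)), 1e-6)
  expect_lt(abs(sum(f$nu$mean * sort(unique(f$nu$year)))), 1e-6)
})

test_that("omitting covariates inflates the estimate under positive confounding", {
  cfg <- small_config(n_counties = 100, years = 1999:2015, seed = 1,
                      true_gamma = log(1.25) / 10,
                      confounding_strength = 0.6,
                      county_confounding = 0.5)
  p <- generate_panel(cfg)
  fu <- stpois(p, "unadjusted", sex = "female", age_group = "70-74")
  fc <- stpois(p, "covariate", sex = "female", age_group = "70-74")
  expect_gt(coef(fu)[["gamma"]], coef(fc)[["gamma"]])
  ## direction confirmed by the independent ML oracle on the same data
  d <- build_design(p, "covariate", sex = "female", age_group = "70-74")
  g1 <- glm(d$y ~ d$t + d$pm, family = poisson,
            offset = log(d$population))
  g2 <- glm(d$y ~ d$t + d$pm + d$X, family = poisson,
            offset = log(d$population))
  expect_gt(coef(g1)[["d$pm"]], coef(g2)[["d$pm"]])
})

test_that("county intercepts are harmless when no heterogeneity exists", {
  p <- generate_panel(small_config(n_counties = 50, seed = 6,
                                   county_intercept_sd = 0))
  fc <- stpois(p, "covariate", sex = "male", age_group = "75-79")
  fcc <- stpois(p, "covariate_county", sex = "male", age_group = "75-79")
  sd_c <- sqrt(vcov(fc)["gamma", "gamma"])
  expect_lt(abs(coef(fcc)[["gamma"]] - coef(fc)[["gamma"]]), sd_c)
})

test_that("the restrictive model ignores shared linear PM-mortality trends", {
  ## counties whose mortality trends are proportional to their PM trends,
  ## with zero true PM effect: models without county slopes see a
  ## spurious association; the restrictive model does not
  C <- 30; years <- 2006:2015; Tn <- length(years)
  set.seed(42)
  lev <- runif(C, 8, 16); dec <- runif(C, 0.2, 0.8)
  counties <- data.frame(county = 1:C, state = 1,
                         urbanicity = "urban")
  edges <- data.frame(from = 1:(C - 1), to = 2:C)
  ex <- expand.grid(county = 1:C, year = years)
  tt <- ex$year - mean(years)
  ex$pm <- pmax(0.5, lev[ex$county] - dec[ex$county] * tt +
                  rnorm(nrow(ex), 0, 0.2))
  for (nm in covariate_names()) ex[[nm]] <- 0
  evg <- expand.grid(county = 1:C, year = years, sex = c("female", "male"),
                     age = age_groups(), stringsAsFactors = FALSE)
  evg$population <- 5000
  tt2 <- evg$year - mean(years)
  lograte <- log(0.02) + 0.08 * dec[evg$county] * tt2  # trend ~ PM decline
  evg$cardio_deaths <- rpois(nrow(evg), 5000 * exp(lograte))
  evg$allcause_deaths <- evg$cardio_deaths +
    rpois(nrow(evg), 5000 * 0.01)
  p <- county_panel(counties, edges, ex, evg)

  ## a maximum-likelihood Poisson regression with county intercepts (the
  ## independent oracle) is fooled by the aligned trends: strongly
  ## negative spurious coefficient
  d <- build_design(p, "unadjusted", sex = "female", age_group = "50-54")
  g <- glm(d$y ~ d$t + d$pm + factor(d$county), family = poisson,
           offset = log(d$population))
  expect_lt(coef(g)[["d$pm"]], -0.03)
  ## the restrictive model, which removes county-specific linear trends,
  ## concentrates near zero
  fr <- stpois(p, "restrictive", sex = "female", age_group = "50-54")
  expect_lt(abs(coef(fr)[["gamma"]]), abs(coef(g)[["d$pm"]]) / 5)
  expect_lt(abs(coef(fr)[["gamma"]]),
            3 * sqrt(vcov(fr)["gamma", "gamma"]))
})

test_that("rate ratios are the exponential of the PM coefficient", {
  ## closed form on a fit object with a degenerate posterior
  f <- structure(list(gamma_draws = rep(log(1.1) / 10, 200)),
                 class = "stpois")
  rr <- rate_ratio(f, delta_pm = 10)
  expect_equal(unname(rr["mean"]), 1.1, tolerance = 1e-12)
  expect_equal(unname(rr["sd"]), 0)
  ## zero coefficient: RR identically 1 at any increment
  f0 <- structure(list(gamma_draws = rep(0, 200)), class = "stpois")
  expect_equal(unname(rate_ratio(f0, 7)["mean"]), 1)
  ## per-1-ug reporting unit is exp(gamma) draw-wise
  p <- generate_panel(small_config(n_counties = 20))
  fit <- stpois(p, "unadjusted", sex = "female", age_group = "85+")
  rr1 <- rate_ratio(fit, 1)
  expect_equal(unname(rr1["50%"]),
               exp(median(fit$gamma_draws)), tolerance = 1e-9)
})

test_that("stratum fan-out fits and labels every requested stratum", {
  p <- generate_panel(small_config(n_counties = 20, years = 2011:2015))
  fits <- fit_strata(p, "unadjusted", sexes = "female",
                     ages = c("70-74", "85+"))
  expect_named(fits, c("female.70-74", "female.85+"))
  expect_true(all(vapply(fits, inherits, TRUE, "stpois")))
  ## summary table is well formed and intervals are ordered
  sm <- summary(fits[["female.85+"]])
  expect_true(all(sm$fixed$`2.5%` <= sm$fixed$`97.5%`))
})
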