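test_that("Kannisto-Thatcher extension recovers a known logistic hazard", {
  a <- 2e-5; b <- 0.105
  mu <- function(x) a * exp(b * x) / (1 + a * exp(b * x))
  fit_ages <- seq(62.5, 82.5, 5)
  ext_mids <- c(seq(87.5, 107.5, 5), 112.5)
  ## open-interval rate consistent with the curve, computed by the
  ## independent stationary-population oracle
  open_rate <- 1 / ext_e85_oracle(mu(ext_mids))
  ext <- kannisto_thatcher_extend(mu(fit_ages), open_rate)
  expect_false(attr(ext, "flagged"))
  expect_equal(as.numeric(ext), mu(ext_mids), tolerance = 1e-6)
})

test_that("flat old-age hazards extend to the open-interval rate", {
  ext <- kannisto_thatcher_extend(rep(0.08, 5), open_interval_rate = 0.08)
  expect_true(attr(ext, "flagged"))  # b = 0 falls back, flagged
  expect_equal(as.numeric(ext), rep(0.08, 6))
  ## near-flat (tiny slope): still constant at the open rate
  m <- 0.08 * exp(1e-9 * (seq(62.5, 82.5, 5) - 72.5))
  ext2 <- kannisto_thatcher_extend(m, 0.08)
  expect_equal(as.numeric(ext2), rep(0.08, 6), tolerance = 1e-6)
})

test_that("extended hazards stay below one per year for any input", {
  set.seed(3)
  for (i in 1:25) {
    m <- sort(runif(5, 0.005, 0.4))
    open_rate <- runif(1, max(m), 0.9)
    ext <- kannisto_thatcher_extend(m, open_rate)
    expect_true(all(ext < 1))
    expect_true(all(ext > 0))
  }
  expect_error(kannisto_thatcher_extend(c(-0.01, rep(0.05, 4)), 0.1),
               "non-positive")
})

test_that("abridged life expectancy matches closed forms and brute force", {
  ## constant hazard 0.02 at every age: e0 = 1/m = 50
  expect_equal(life_expectancy(rep(0.02, 18)), 50, tolerance = 0.5)
  ## zero mortality before 85 and flat extension at m: e0 = 85 + 1/m
  expect_equal(life_expectancy(c(rep(0, 17), 0.1)), 95, tolerance = 0.25)
  ## doubling every rate strictly lowers e0
  m <- default_allcause_rates()["female", ]
  expect_lt(life_expectancy(2 * m), life_expectancy(m))

  ## brute-force single-year oracle on random hazard schedules
  set.seed(11)
  for (i in 1:30) {
    base <- exp(log(2e-4) + cumsum(runif(18, 0.05, 0.45)))
    base <- pmin(base, 0.6)
    lt <- build_lifetable(base)
    e_brute <- brute_force_e0(lt$mx, lt$age_lo)
    expect_lt(abs(attr(lt, "e0") - e_brute), 0.5)
  }
})

test_that("lifetable columns satisfy the internal identities", {
  lt <- build_lifetable(default_allcause_rates()["male", ])
  expect_true(all(lt$qx >= 0 & lt$qx <= 1))
  expect_true(all(diff(lt$lx) <= 0))
  expect_equal(lt$Tx, rev(cumsum(rev(lt$Lx))))
  expect_equal(attr(lt, "e0"), lt$ex[1])
  expect_gt(attr(lt, "e0"), 0)
  expect_error(build_lifetable(rep(-0.01, 18)), "negative")
  expect_error(build_lifetable(rep(0.01, 10)), "18")
})

test_that("life-expectancy loss is zero iff no deaths are averted", {
  p <- make_toy_panel(pops = rep(90000, 4), pm = c(4, 7, 10, 13),
                      cardio_rate = 0.004, allcause_rate = 0.01)
  att0 <- scenario_attribution(p, make_const_fits(0), scenario_floor(p, 2.8))
  ll0 <- le_loss(p, att0, "national")
  expect_equal(ll0$loss_mean, c(0, 0))
  expect_equal(ll0$loss_lo, c(0, 0))

  att <- scenario_attribution(p, make_const_fits(0.02),
                              scenario_floor(p, 2.8))
  ll <- le_loss(p, att, "national")
  expect_true(all(ll$loss_mean > 0))
  ## counterfactual e0 exceeds observed when deaths are averted
  expect_true(all(ll$e0_counterfactual > ll$e0_observed))
})

test_that("the loss equals an independent lifetable difference", {
  gam <- 0.03
  p <- make_toy_panel(pops = rep(90000, 2), pm = c(12, 5),
                      cardio_rate = 0.004, allcause_rate = 0.011)
  att <- scenario_attribution(p, make_const_fits(gam),
                              scenario_floor(p, 2.8))
  ll <- le_loss(p, att, "national", sexes = "female")
  ## brute-force oracle: recompute pooled observed and counterfactual
  ## rates by hand from the raw tables and difference the lifetables
  ev <- p$events[p$events$year == 2015 & p$events$sex == "female", ]
  d_all <- tapply(ev$allcause_deaths, ev$age, sum)[age_groups()]
  pop <- tapply(ev$population, ev$age, sum)[age_groups()]
  pm_by_cty <- c(12, 5)
  av <- tapply(ev$cardio_deaths *
                 (1 - exp(gam * (2.8 - pm_by_cty[ev$county]))),
               ev$age, sum)[age_groups()]
  loss_oracle <- life_expectancy((d_all - av) / pop) -
    life_expectancy(d_all / pop)
  expect_equal(ll$loss_mean, loss_oracle, tolerance = 1e-10)
})

test_that("county losses bracket the national loss", {
  p <- generate_panel(small_config(n_counties = 20, years = 2012:2015,
                                   pop_meanlog = log(2e5)))
  att <- scenario_attribution(p, make_const_fits(0.02, n_draws = 20),
                              scenario_floor(p, 2.8))
  nat <- le_loss(p, att, "national", sexes = "female")
  cty <- le_loss(p, att, "county", sexes = "female")
  expect_gte(nat$loss_mean, min(cty$loss_mean) - 1e-9)
  expect_lte(nat$loss_mean, max(cty$loss_mean) + 1e-9)
})
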