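test_that("counties above threshold are left untouched (identity plan)", {
  p <- make_toy_panel(pops = c(30000, 40000, 50000), pm = c(5, 8, 11),
                      edges = data.frame(from = c(1, 2), to = c(2, 3)))
  m <- merge_small_counties(p, threshold = 25000)
  expect_identical(m$panel, p)
  expect_equal(m$plan$mapping$original, m$plan$mapping$merged)
})

test_that("a deficient county merges with its neighbour, PM population-weighted", {
  ## 3-county chain: sex-specific populations 10,080 / 30,240 / 40,320
  ## (divisible by 18 so cell populations are exact), edges 1-2, 2-3
  pm <- c(4, 10, 7)
  p <- make_toy_panel(pops = c(10080, 30240, 40320), pm = pm,
                      edges = data.frame(from = c(1, 2), to = c(2, 3)))
  m <- merge_small_counties(p, threshold = 25000)
  map <- m$plan$mapping
  expect_equal(map$merged[map$original == 1], 1)
  expect_equal(map$merged[map$original == 2], 1)
  expect_equal(map$merged[map$original == 3], 3)
  pm_merged <- m$panel$exposure$pm[m$panel$exposure$county == 1][1]
  expect_equal(pm_merged, (10080 * 4 + 30240 * 10) / 40320,
               tolerance = 1e-12)
  ## merged PM lies within member range
  expect_true(pm_merged >= min(pm[1:2]) && pm_merged <= max(pm[1:2]))
})

test_that("merging conserves deaths and population and meets the threshold", {
  for (s in c(1, 4)) {
    p <- generate_panel(small_config(n_counties = 30, seed = s,
                                     pop_meanlog = log(35000)))
    m <- merge_small_counties(p, threshold = 25000)
    mp <- m$panel
    ## conservation per sex-year-age
    key <- function(ev) paste(ev$sex, ev$year, ev$age)
    a <- tapply(p$events$population, key(p$events), sum)
    b <- tapply(mp$events$population, key(mp$events), sum)
    expect_equal(b[names(a)], a)
    a <- tapply(p$events$allcause_deaths, key(p$events), sum)
    b <- tapply(mp$events$allcause_deaths, key(mp$events), sum)
    expect_equal(b[names(a)], a)

    ## threshold audit: every unflagged unit exceeds the threshold in
    ## every sex-year
    ev <- mp$events
    sy <- tapply(ev$population, paste(ev$county, ev$sex, ev$year), sum)
    units <- m$plan$units
    ok_units <- units$merged[!units$unmergeable]
    for (u in ok_units) {
      vals <- sy[grep(paste0("^", u, " "), names(sy))]
      expect_gte(min(vals), 25000)
    }

    ## no unit crosses state or urban/rural boundaries
    st <- setNames(p$counties$state, p$counties$county)
    ur <- setNames(p$counties$urbanicity, p$counties$county)
    map <- m$plan$mapping
    for (u in unique(map$merged)) {
      mem <- map$original[map$merged == u]
      expect_length(unique(st[as.character(mem)]), 1)
      expect_length(unique(ur[as.character(mem)]), 1)
    }

    ## units are connected under the original adjacency
    nbmat <- rbind(as.matrix(p$adjacency), as.matrix(p$adjacency)[, 2:1])
    for (u in unique(map$merged)) {
      mem <- map$original[map$merged == u]
      if (length(mem) == 1) next
      seen <- mem[1]
      repeat {
        nxt <- unique(nbmat[nbmat[, 1] %in% seen, 2])
        grow <- intersect(setdiff(nxt, seen), mem)
        if (!length(grow)) break
        seen <- c(seen, grow)
      }
      expect_setequal(seen, mem)
    }

    ## idempotence: merging the merged panel is the identity
    m2 <- merge_small_counties(mp, threshold = 25000)
    expect_equal(m2$plan$mapping$original, m2$plan$mapping$merged)
  }
})

test_that("counties with no eligible neighbour are flagged, not merged", {
  ## two small counties in different states: neither can merge
  p <- make_toy_panel(pops = c(10000, 12000), pm = c(5, 6),
                      state = c(1, 2),
                      edges = data.frame(from = 1, to = 2))
  m <- merge_small_counties(p, threshold = 25000)
  expect_true(all(m$plan$units$unmergeable))
  expect_equal(nrow(m$plan$units), 2)
})

test_that("age-standardised rates follow the weighted-rate definition", {
  ## equal rates give the common rate regardless of weights
  expect_equal(age_standardised_rate(c(20, 40), c(10000, 20000),
                                     c(0.3, 0.7)), 0.002 * 1e5)
  ## two ages, rates 0.001 and 0.003, equal weights -> 200 per 100,000
  expect_equal(age_standardised_rate(c(10, 30), c(10000, 10000),
                                     c(0.5, 0.5)), 200)
  expect_equal(age_standardised_rate(c(0, 0), c(1000, 1000)), 0)
  expect_error(age_standardised_rate(c(1, 1), c(0, 1000), c(0.5, 0.5)),
               "zero population")
  expect_error(age_standardised_rate(c(1, 1), c(10, 10), c(0.5, 0.6)),
               "sum to 1")
})
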