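## Unit-of-analysis construction: recursive merging of small counties and
## population-weighted aggregation of exposure and covariates.

#' Recursively merge small counties into stable analysis units
#'
#' Counties whose sex-specific population falls below \code{threshold} in
#' any year are merged with a neighbouring county until all sex-year
#' populations surpass the threshold, never crossing state boundaries nor
#' combining urban and rural counties. Deaths and populations are summed
#' over members; PM2.5 and covariates become population-weighted means
#' (log-transformed covariates are averaged on the natural scale and
#' re-logged). Counties with no eligible neighbour are left unmerged and
#' flagged.
#'
#' Merge order: the currently smallest deficient unit (by its minimum
#' sex-year population) is merged with its smallest eligible neighbour;
#' ties break by lowest unit id. The merged unit keeps the smaller member
#' id, and unit adjacency is the union of member adjacency.
#'
#' @param panel A \code{county_panel}.
#' @param threshold Minimum sex-specific population (persons) each unit
#'   must reach in every year.
#' @return A list with elements \code{panel} (the merged
#'   \code{county_panel}) and \code{plan} (a \code{merge_plan}: mapping
#'   from original to merged ids, unit membership, and an
#'   \code{unmergeable} flag per unit).
#' @examples
#' p <- generate_panel(panel_config(n_counties = 20, seed = 3))
#' m <- merge_small_counties(p, threshold = 25000)
#' head(m$plan$mapping)
#' @export
merge_small_counties <- function(panel, threshold = 25000) {
  stopifnot(inherits(panel, "county_panel"), threshold > 0)
  ids <- panel$counties$county
  C <- length(ids)
  ev <- panel$events

  ## sex-year population matrix per original county
  key_sy <- paste(ev$sex, ev$year)
  sy_levels <- sort(unique(key_sy))
  pop_sy <- matrix(0, C, length(sy_levels),
                   dimnames = list(as.character(ids), sy_levels))
  agg <- tapply(ev$population, list(paste(ev$county), key_sy), sum)
  pop_sy[rownames(agg), colnames(agg)] <- agg

  nb <- neighbour_list(panel)
  state <- stats::setNames(panel$counties$state, as.character(ids))
  urb <- stats::setNames(panel$counties$urbanicity, as.character(ids))

  ## live units keyed by representative (minimum member) id
  members <- stats::setNames(as.list(ids), as.character(ids))
  unit_pop <- pop_sy
  unit_nb <- lapply(nb, identity)
  flagged <- stats::setNames(rep(FALSE, C), as.character(ids))
  alive <- stats::setNames(rep(TRUE, C), as.character(ids))

  repeat {
    live <- names(alive)[alive]
    minpop <- apply(unit_pop[live, , drop = FALSE], 1, min)
    deficient <- live[minpop < threshold & !flagged[live]]
    if (!length(deficient)) break
    ## smallest deficient unit, ties by lowest id
    o <- order(minpop[deficient], as.numeric(deficient))
    u <- deficient[o[1]]
    cand <- as.character(unit_nb[[u]])
    cand <- cand[alive[cand] & state[cand] == state[u] &
                   urb[cand] == urb[u]]
    if (!length(cand)) { flagged[u] <- TRUE; next }
    cp <- apply(unit_pop[cand, , drop = FALSE], 1, min)
    v <- cand[order(cp, as.numeric(cand))][1]
    keep <- as.character(min(as.numeric(c(u, v))))
    drop <- setdiff(c(u, v), keep)
    members[[keep]] <- sort(c(members[[keep]], members[[drop]]))
    unit_pop[keep, ] <- unit_pop[u, ] + unit_pop[v, ]
    merged_nb <- setdiff(union(unit_nb[[u]], unit_nb[[v]]),
                         as.numeric(c(u, v)))
    unit_nb[[keep]] <- merged_nb
    for (w in as.character(merged_nb)) {
      unit_nb[[w]] <- union(setdiff(unit_nb[[w]], as.numeric(drop)),
                            as.numeric(keep))
    }
    alive[drop] <- FALSE
    members[[drop]] <- NULL
  }

  live <- names(alive)[alive]
  mapping <- data.frame(
    original = unlist(members, use.names = FALSE),
    merged = rep(as.numeric(live),
                 vapply(members[live], length, 0L)))
  mapping <- mapping[order(mapping$original), ]
  rownames(mapping) <- NULL

  plan <- structure(list(
    mapping = mapping,
    units = data.frame(
      merged = as.numeric(live),
      n_members = vapply(members[live], length, 0L),
      state = state[live], urbanicity = urb[live],
      unmergeable = flagged[live], row.names = NULL),
    threshold = threshold), class = "merge_plan")

  if (nrow(mapping) == sum(mapping$original == mapping$merged) &&
      all(mapping$original == mapping$merged))
    return(list(panel = panel, plan = plan))

  ## aggregate tables to merged units
  map <- stats::setNames(mapping$merged, as.character(mapping$original))
  evm <- ev
  evm$county <- as.numeric(map[as.character(ev$county)])
  events <- stats::aggregate(
    cbind(population, cardio_deaths, allcause_deaths) ~
      county + year + sex + age, data = evm, FUN = sum)

  ex <- panel$exposure
  w <- county_year_population(panel)
  exm <- ex
  exm$county <- as.numeric(map[as.character(ex$county)])
  log_cols <- grep("^log_", covariate_names(), value = TRUE)
  vals <- ex[, c("pm", covariate_names())]
  for (cc in log_cols) vals[[cc]] <- exp(vals[[cc]])
  wv <- vals * w
  wv$w <- w
  agg2 <- stats::aggregate(wv, by = list(county = exm$county,
                                         year = exm$year), FUN = sum)
  for (cc in c("pm", covariate_names())) agg2[[cc]] <- agg2[[cc]] / agg2$w
  for (cc in log_cols) agg2[[cc]] <- log(agg2[[cc]])
  exposure <- agg2[, c("county", "year", "pm", covariate_names())]

  counties <- data.frame(county = as.numeric(live),
                         state = state[live], urbanicity = urb[live],
                         row.names = NULL)
  pairs <- unique(do.call(rbind, lapply(live, function(u) {
    nbv <- as.numeric(unit_nb[[u]])
    if (!length(nbv)) return(NULL)
    cbind(pmin(as.numeric(u), nbv), pmax(as.numeric(u), nbv))
  })))
  adjacency <- if (is.null(pairs)) data.frame(from = numeric(0),
                                              to = numeric(0))
  else data.frame(from = pairs[, 1], to = pairs[, 2])

  merged_panel <- county_panel(counties, adjacency, exposure, events,
                               config = panel$config, merged = TRUE)
  list(panel = merged_panel, plan = plan)
}

#' @export
print.merge_plan <- function(x, ...) {
  cat(sprintf("Merge plan: %d original counties -> %d units (threshold %s)\n",
              nrow(x$mapping), nrow(x$units),
              format(x$threshold, big.mark = ",")))
  if (any(x$units$unmergeable))
    cat(sprintf("  %d unit(s) flagged unmergeable\n",
                sum(x$units$unmergeable)))
  invisible(x)
}

#' Age-standardised death rate per 100,000
#'
#' Weighted average of age-specific death rates using a standard age
#' distribution, as used to construct the log lung-cancer death-rate
#' proxy for cumulative smoking.
#'
#' @param deaths Death counts by age group.
#' @param population Person-years by age group (all > 0 where the weight
#'   is nonzero).
#' @param weights Standard-population weights (must sum to 1). Default:
#'   equal weights.
#' @return Standardised rate per 100,000.
#' @examples
#' age_standardised_rate(c(10, 30), c(10000, 10000), c(0.5, 0.5))
#' @export
age_standardised_rate <- function(deaths, population,
                                  weights = rep(1 / length(deaths),
                                                length(deaths))) {
  stopifnot(length(deaths) == length(population),
            length(deaths) == length(weights))
  if (abs(sum(weights) - 1) > 1e-8) stop("weights must sum to 1")
  if (any(population <= 0 & weights > 0))
    stop("zero population in an age group with nonzero weight")
  rate <- ifelse(weights > 0, deaths / population, 0)
  sum(weights * rate) * 1e5
}
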