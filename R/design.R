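## Model specification and design construction for the four
## spatiotemporal Poisson models.

#' Specify one of the four spatiotemporal mortality models
#'
#' The four models share the structure
#' \code{log(rate) = alpha0 + beta0*year + nu_year [+ alpha_county
#' [+ beta_county*year]] + gamma*PM [+ sum(theta_i X_i)] + eps} and differ
#' in how far they adjust for county characteristics: \code{"unadjusted"}
#' has no covariates or county terms; \code{"covariate"} adds the nine
#' time-varying covariates; \code{"covariate_county"} further adds CAR
#' county random intercepts (the difference-in-difference-like main
#' model); \code{"restrictive"} also adds CAR county random time slopes.
#'
#' @param name One of \code{"unadjusted"}, \code{"covariate"},
#'   \code{"covariate_county"}, \code{"restrictive"}.
#' @return A \code{model_spec} with logical flags
#'   \code{include_covariates}, \code{include_county_intercepts},
#'   \code{include_county_slopes}.
#' @export
model_spec <- function(name = c("unadjusted", "covariate",
                                "covariate_county", "restrictive")) {
  name <- match.arg(name)
  flags <- switch(name,
    unadjusted = c(FALSE, FALSE, FALSE),
    covariate = c(TRUE, FALSE, FALSE),
    covariate_county = c(TRUE, TRUE, FALSE),
    restrictive = c(TRUE, TRUE, TRUE))
  structure(list(name = name,
                 include_covariates = flags[1],
                 include_county_intercepts = flags[2],
                 include_county_slopes = flags[3]),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("Model '%s': covariates=%s, county intercepts=%s, county slopes=%s\n",
              x$name, x$include_covariates, x$include_county_intercepts,
              x$include_county_slopes))
  invisible(x)
}

#' Build model inputs for one sex-age stratum
#'
#' Extracts, for the chosen sex and age group, the response counts,
#' population offsets, year index centred at the panel mid-year, PM2.5
#' vector, covariate matrix (when the spec includes covariates) and the
#' county adjacency structure used by the CAR random effects. Rows are
#' ordered by county within year.
#'
#' @param panel A \code{county_panel}.
#' @param spec A \code{model_spec} (or its name).
#' @param sex \code{"female"} or \code{"male"}.
#' @param age_group One of \code{age_groups()}.
#' @return A list of class \code{stpois_design}.
#' @export
build_design <- function(panel, spec, sex = c("female", "male"),
                         age_group = "85+") {
  stopifnot(inherits(panel, "county_panel"))
  if (is.character(spec)) spec <- model_spec(spec)
  sex <- match.arg(sex)
  if (!age_group %in% age_groups()) stop("unknown age group: ", age_group)

  ev <- panel$events
  ev <- ev[ev$sex == sex & ev$age == age_group, ]
  if (nrow(ev) == 0) stop("panel has no cells for this sex/age stratum")
  if (any(ev$population <= 0))
    stop("zero population cell in stratum; run merge_small_counties() first")

  ids <- sort(panel$counties$county)
  years <- panel$years
  ev <- ev[order(ev$year, ev$county), ]
  if (nrow(ev) != length(ids) * length(years))
    stop("stratum is incomplete over the county-year grid")

  ex <- panel$exposure
  key <- paste(ex$county, ex$year)
  at <- match(paste(ev$county, ev$year), key)
  pm <- ex$pm[at]
  X <- NULL
  if (spec$include_covariates) {
    miss <- setdiff(covariate_names(), names(ex))
    if (length(miss))
      stop("missing covariates required by this model: ",
           paste(miss, collapse = ", "))
    X <- as.matrix(ex[at, covariate_names()])
  }

  structure(list(
    y = ev$cardio_deaths, population = ev$population,
    year = ev$year, t = ev$year - mean(years),
    county = ev$county,
    county_index = match(ev$county, ids),
    year_index = match(ev$year, years),
    pm = pm, X = X,
    county_ids = ids, years = years,
    adjacency = panel$adjacency,
    spec = spec, sex = sex, age_group = age_group), class = "stpois_design")
}
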