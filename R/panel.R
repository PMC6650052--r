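## CountyPanel container: the county x year x sex x age observational array
## with exposure, covariates, adjacency, state and urbanicity.

#' Construct a county panel
#'
#' Bundles the four tables the analysis needs and checks their joint
#' invariants: a county table (id, state, urbanicity), a symmetric
#' self-edge-free adjacency edge list, a county-year exposure table (PM2.5
#' and the nine covariates), and a county-year-sex-age events table
#' (population, cardiorespiratory and all-cause deaths).
#'
#' @param counties data.frame with columns \code{county}, \code{state},
#'   \code{urbanicity} (\code{"urban"}/\code{"rural"}).
#' @param adjacency data.frame of undirected edges with columns \code{from},
#'   \code{to} (county ids); each edge may be listed once.
#' @param exposure data.frame with columns \code{county}, \code{year},
#'   \code{pm} and the nine covariates of \code{covariate_names()}.
#' @param events data.frame with columns \code{county}, \code{year},
#'   \code{sex}, \code{age}, \code{population}, \code{cardio_deaths},
#'   \code{allcause_deaths}.
#' @param config Optional \code{panel_config} the panel was generated from.
#' @param merged Logical; whether the panel is the product of
#'   \code{merge_small_counties()}.
#'
#' @return An object of class \code{county_panel}.
#' @export
county_panel <- function(counties, adjacency, exposure, events,
                         config = NULL, merged = FALSE) {
  counties <- as.data.frame(counties)
  adjacency <- as.data.frame(adjacency)
  exposure <- as.data.frame(exposure)
  events <- as.data.frame(events)
  stopifnot(all(c("county", "state", "urbanicity") %in% names(counties)),
            all(c("from", "to") %in% names(adjacency)) || nrow(adjacency) == 0,
            all(c("county", "year", "pm") %in% names(exposure)),
            all(c("county", "year", "sex", "age", "population",
                  "cardio_deaths", "allcause_deaths") %in% names(events)))
  if (nrow(events) == 0 || nrow(exposure) == 0)
    stop("empty panel: exposure and events tables must be non-empty")
  ids <- counties$county
  if (anyDuplicated(ids)) stop("duplicate county ids")
  if (nrow(adjacency)) {
    if (any(adjacency$from == adjacency$to))
      stop("adjacency contains self-edges")
    if (!all(adjacency$from %in% ids) || !all(adjacency$to %in% ids))
      stop("adjacency references unknown county ids")
  }
  if (any(exposure$pm < 0)) stop("negative PM2.5 concentration")
  if (any(events$population <= 0))
    stop("non-positive population cell; merge small counties first")
  if (any(events$cardio_deaths < 0) || any(events$allcause_deaths < 0))
    stop("negative death counts")
  if (any(events$cardio_deaths > events$allcause_deaths))
    stop("cardiorespiratory deaths exceed all-cause deaths in some cells")
  if (any(events$allcause_deaths > events$population))
    stop("deaths exceed population in some cells")
  years <- sort(unique(exposure$year))
  full <- nrow(exposure) == length(ids) * length(years)
  if (!full) stop("exposure table has missing county-year cells")
  n_cells <- length(ids) * length(years) * 2 * 18
  if (nrow(events) != n_cells)
    stop("events table has missing county-year-sex-age cells")
  structure(list(counties = counties, adjacency = adjacency,
                 exposure = exposure, events = events,
                 years = years, config = config, merged = merged),
            class = "county_panel")
}

#' @export
print.county_panel <- function(x, ...) {
  cat(sprintf(paste0("County panel: %d %s, %d-%d, 2 sexes x %d age groups",
                     " (%s cells)\n"),
              nrow(x$counties), if (isTRUE(x$merged)) "merged units"
              else "counties",
              min(x$years), max(x$years), 18,
              format(nrow(x$events), big.mark = ",")))
  pw <- vapply(range(x$years), function(y) pm_weighted_mean(x, y), 0)
  cat(sprintf("  population-weighted PM2.5: %.1f (%d) -> %.1f (%d) ug/m3\n",
              pw[1], min(x$years), pw[2], max(x$years)))
  cat(sprintf("  total deaths: %s all-cause, %s cardiorespiratory\n",
              format(sum(x$events$allcause_deaths), big.mark = ","),
              format(sum(x$events$cardio_deaths), big.mark = ",")))
  invisible(x)
}

#' Population-weighted mean PM2.5 across counties in one year
#'
#' @param panel A \code{county_panel}.
#' @param year Calendar year.
#' @return Mean PM2.5 (ug/m3) weighted by county total population.
#' @export
pm_weighted_mean <- function(panel, year) {
  ev <- panel$events[panel$events$year == year, ]
  pop <- tapply(ev$population, ev$county, sum)
  ex <- panel$exposure[panel$exposure$year == year, ]
  pm <- ex$pm[match(names(pop), as.character(ex$county))]
  sum(pm * pop) / sum(pop)
}

## Total population per county-year (both sexes, all ages), aligned with
## the exposure table rows.
county_year_population <- function(panel) {
  ev <- panel$events
  key <- paste(ev$county, ev$year)
  pop <- tapply(ev$population, key, sum)
  as.numeric(pop[paste(panel$exposure$county, panel$exposure$year)])
}

## Neighbour list (by county id) from the adjacency edge table.
neighbour_list <- function(panel) {
  ids <- panel$counties$county
  nb <- stats::setNames(vector("list", length(ids)), as.character(ids))
  for (i in seq_along(nb)) nb[[i]] <- integer(0)
  if (nrow(panel$adjacency)) {
    a <- panel$adjacency
    for (k in seq_len(nrow(a))) {
      f <- as.character(a$from[k]); t <- as.character(a$to[k])
      nb[[f]] <- union(nb[[f]], a$to[k])
      nb[[t]] <- union(nb[[t]], a$from[k])
    }
  }
  nb
}

#' Write a county panel to tabular text files
#'
#' Emits four CSV files: \code{<prefix>_counties.csv},
#' \code{<prefix>_adjacency.csv} (edge list), \code{<prefix>_exposure.csv}
#' and \code{<prefix>_events.csv}.
#'
#' @param panel A \code{county_panel}.
#' @param dir Output directory (created if missing).
#' @param prefix File-name prefix.
#' @return Invisibly, the four file paths.
#' @export
write_panel <- function(panel, dir, prefix = "panel") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, paste0(prefix, "_",
                                 c("counties", "adjacency",
                                   "exposure", "events"), ".csv"))
  utils::write.csv(panel$counties, paths[1], row.names = FALSE)
  utils::write.csv(panel$adjacency, paths[2], row.names = FALSE)
  utils::write.csv(panel$exposure, paths[3], row.names = FALSE)
  utils::write.csv(panel$events, paths[4], row.names = FALSE)
  invisible(paths)
}

#' Read a county panel written by \code{write_panel()}
#'
#' @param dir Directory containing the files.
#' @param prefix File-name prefix used when writing.
#' @return A \code{county_panel}.
#' @export
read_panel <- function(dir, prefix = "panel") {
  rd <- function(what) utils::read.csv(
    file.path(dir, paste0(prefix, "_", what, ".csv")))
  county_panel(rd("counties"), rd("adjacency"), rd("exposure"), rd("events"))
}
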