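## Abridged lifetables with Kannisto-Thatcher extension of the open 85+
## interval, and conversion of averted deaths into life-expectancy loss.

## a_x: average years lived within the interval by those dying in it.
## The first (0-4) interval uses 2.0 (early-childhood deaths concentrate
## at young ages within the interval); all later 5-year intervals use 2.5.
ax_values <- function(k) c(2.0, rep(2.5, k - 1))

## Stationary-population remaining life expectancy at 85 implied by a set
## of extension rates (piecewise-constant hazard in 5-year bands, open
## final interval).
ext_e85 <- function(rates) {
  nb <- length(rates) - 1
  l <- 1
  e <- 0
  for (j in seq_len(nb)) {
    m <- rates[j]
    if (m <= 0) { e <- e + 5 * l; next }
    l_next <- l * exp(-5 * m)
    e <- e + l * (1 - exp(-5 * m)) / m
    l <- l_next
  }
  m_open <- rates[nb + 1]
  if (m_open > 0) e <- e + l / m_open
  e
}

#' Kannisto-Thatcher extension of old-age death rates
#'
#' Fits the logistic hazard \code{mu(x) = a e^(bx) / (1 + a e^(bx))} to
#' the old-age death rates (default fitting ages 60-84, at 5-year
#' interval midpoints) by least squares on the logit scale, then rescales
#' the level \code{a} so that the life expectancy implied by the extended
#' schedule reproduces the observed open-interval (85+) rate, i.e. the
#' extension's stationary-population-weighted mean rate equals the
#' observed rate. Returns rates for 85-89 through 105-109 plus an open
#' 110+ interval; the logistic form keeps every extended hazard below 1
#' per year.
#'
#' If the fitted slope is non-positive (non-increasing old-age rates) the
#' extension falls back to a constant at the open-interval rate and is
#' flagged.
#'
#' @param old_age_rates Central death rates for the fitting ages
#'   (default: five 5-year intervals, 60-64 through 80-84).
#' @param open_interval_rate Observed central death rate of the 85+ group.
#' @param fit_ages Midpoints (years) of the fitting intervals.
#' @return Named vector of six rates (\code{"85-89"} ... \code{"105-109"},
#'   \code{"110+"}) with attributes \code{a}, \code{b}, \code{scale} and
#'   \code{flagged}.
#' @examples
#' m <- c(0.010, 0.016, 0.026, 0.042, 0.066)
#' kannisto_thatcher_extend(m, open_interval_rate = 0.15)
#' @export
kannisto_thatcher_extend <- function(old_age_rates, open_interval_rate,
                                     fit_ages = seq(62.5, 82.5, by = 5)) {
  stopifnot(length(old_age_rates) == length(fit_ages))
  if (any(old_age_rates <= 0) || open_interval_rate <= 0)
    stop("non-positive death rates cannot be extended")
  if (any(old_age_rates >= 1))
    stop("old-age central death rates must be below 1 per year")
  ext_mids <- seq(87.5, 107.5, by = 5)
  open_mid <- 112.5

  lx <- log(old_age_rates / (1 - old_age_rates))
  b <- stats::cov(fit_ages, lx) / stats::var(fit_ages)
  flagged <- FALSE
  if (!is.finite(b) || b <= 0) {
    rates <- rep(open_interval_rate, length(ext_mids) + 1)
    names(rates) <- c(paste(ext_mids - 2.5, ext_mids + 2.5, sep = "-"),
                      "110+")
    attr(rates, "a") <- NA_real_; attr(rates, "b") <- 0
    attr(rates, "scale") <- NA_real_; attr(rates, "flagged") <- TRUE
    return(rates)
  }
  log_a <- mean(lx) - b * mean(fit_ages)

  mu_at <- function(log_s) {
    u <- exp(pmin(log_s + log_a + b * c(ext_mids, open_mid), 700))
    u / (1 + u)
  }
  target <- function(log_s) ext_e85(mu_at(log_s)) - 1 / open_interval_rate
  root <- tryCatch(
    stats::uniroot(target, lower = -15, upper = 15, tol = 1e-13),
    error = function(e) NULL)
  if (is.null(root)) {
    rates <- rep(open_interval_rate, length(ext_mids) + 1)
    names(rates) <- c(paste(ext_mids - 2.5, ext_mids + 2.5, sep = "-"),
                      "110+")
    attr(rates, "a") <- exp(log_a); attr(rates, "b") <- b
    attr(rates, "scale") <- NA_real_; attr(rates, "flagged") <- TRUE
    return(rates)
  }
  rates <- mu_at(root$root)
  names(rates) <- c(paste(ext_mids - 2.5, ext_mids + 2.5, sep = "-"),
                    "110+")
  attr(rates, "a") <- exp(log_a); attr(rates, "b") <- b
  attr(rates, "scale") <- exp(root$root); attr(rates, "flagged") <- FALSE
  rates
}

#' Build an abridged lifetable
#'
#' Converts 18 age-specific central death rates (five-year groups, open
#' 85+) into a standard abridged lifetable with the open interval
#' expanded to 110+ by the Kannisto-Thatcher method. Probabilities use
#' \code{q = n m / (1 + (n - a) m)} with \code{n = 5} and \code{a} from
#' \code{ax_values}; the final open interval uses \code{L = l / m}.
#'
#' @param mx Central death rates for the 18 age groups of
#'   \code{age_groups()}.
#' @param population Optional person-years by age (only validated, not
#'   used in the calculation).
#' @return An object of class \code{lifetable}: a data.frame with columns
#'   \code{age}, \code{mx}, \code{qx}, \code{lx}, \code{dx}, \code{Lx},
#'   \code{Tx}, \code{ex}, with attributes \code{e0} and \code{kt}
#'   (extension details).
#' @examples
#' lt <- build_lifetable(rep(0.02, 18))
#' attr(lt, "e0")  # ~50 years under a constant hazard of 0.02
#' @export
build_lifetable <- function(mx, population = NULL) {
  if (length(mx) != 18) stop("expected 18 age-specific death rates")
  if (any(mx < 0)) stop("negative death rate")
  if (!is.null(population) && any(population <= 0))
    stop("non-positive population")

  fit_rates <- mx[13:17]           # ages 60-84
  open_rate <- mx[18]
  ext <- if (all(fit_rates > 0) && open_rate > 0)
    tryCatch(kannisto_thatcher_extend(fit_rates, open_rate),
             error = function(e) NULL) else NULL
  if (is.null(ext)) {
    ext <- rep(open_rate, 6)
    names(ext) <- c("85-89", "90-94", "95-99", "100-104", "105-109",
                    "110+")
    attr(ext, "flagged") <- TRUE
  }

  rates <- c(mx[1:17], ext)
  k <- length(rates)
  ages_lo <- c(seq(0, 80, 5), seq(85, 110, 5))
  labels <- c(age_groups()[1:17], names(ext))
  ax <- ax_values(k)
  n <- 5
  qx <- (n * rates) / (1 + (n - ax) * rates)
  qx <- pmin(qx, 1)
  qx[k] <- 1
  lx <- numeric(k)
  lx[1] <- 1e5
  for (i in seq_len(k - 1)) lx[i + 1] <- lx[i] * (1 - qx[i])
  dx <- lx * qx
  Lx <- numeric(k)
  Lx[1:(k - 1)] <- n * lx[2:k] + ax[1:(k - 1)] * dx[1:(k - 1)]
  Lx[k] <- if (rates[k] > 0) lx[k] / rates[k] else 0
  Tx <- rev(cumsum(rev(Lx)))
  ex <- ifelse(lx > 0, Tx / lx, 0)
  out <- data.frame(age = labels, age_lo = ages_lo, mx = unname(rates),
                    qx = qx, lx = lx, dx = dx, Lx = Lx, Tx = Tx, ex = ex)
  structure(out, class = c("lifetable", "data.frame"),
            e0 = ex[1], kt = ext)
}

#' @export
print.lifetable <- function(x, digits = 4, ...) {
  cat(sprintf("Abridged lifetable (e0 = %.2f years)\n", attr(x, "e0")))
  print.data.frame(cbind(x["age"], round(x[-(1:2)], digits)),
                   row.names = FALSE)
  invisible(x)
}

#' Life expectancy at birth from 18 age-specific rates
#'
#' @param mx Central death rates for the 18 standard age groups.
#' @return Life expectancy at birth in years.
#' @export
life_expectancy <- function(mx) attr(build_lifetable(mx), "e0")

#' Life-expectancy loss attributable to PM2.5
#'
#' For each unit (each county, or the national pool) and sex, builds the
#' observed lifetable from all-cause death rates and, per posterior draw,
#' the counterfactual lifetable after subtracting the averted
#' cardiorespiratory deaths from the all-cause counts. The loss is
#' \code{counterfactual e0 - observed e0}, summarised as the posterior
#' mean and 95% interval of the draw-level losses (life expectancy is
#' nonlinear in the rates, so the loss is computed per draw and then
#' summarised). Draws in which averted deaths would exceed a cell's
#' cardiorespiratory deaths are clipped to the cardiorespiratory count
#' and flagged.
#'
#' @param panel A \code{county_panel}.
#' @param attribution A \code{pm_attribution} from
#'   \code{scenario_attribution()}.
#' @param unit \code{"national"} (pooled deaths and population) or
#'   \code{"county"}.
#' @param sexes Sexes to evaluate.
#' @param max_draws Cap on the number of posterior draws used (county-level
#'   tables across many units can otherwise be slow).
#' @return An object of class \code{le_loss}: a data.frame with one row
#'   per unit and sex (observed e0, counterfactual e0 and loss with 95%
#'   interval) plus attributes \code{draws} (loss draws per row) and
#'   \code{clipped}.
#' @export
le_loss <- function(panel, attribution, unit = c("national", "county"),
                    sexes = c("female", "male"),
                    max_draws = if (match.arg(unit) == "county") 250
                    else Inf) {
  unit <- match.arg(unit)
  stopifnot(inherits(attribution, "pm_attribution"))
  yr <- attribution$years
  ev <- panel$events[panel$events$year %in% yr, ]
  ids <- sort(panel$counties$county)
  R <- min(attribution$n_draws, max_draws)
  clipped <- FALSE
  rows <- list(); loss_draws <- list()
  for (s in sexes) {
    arr <- attribution$draws[[s]][, , seq_len(R), drop = FALSE]
    evs <- ev[ev$sex == s, ]
    ## all-cause deaths, cardio deaths and population: county x age
    D_all <- with(evs, tapply(allcause_deaths, list(county, age), sum))
    D_card <- with(evs, tapply(cardio_deaths, list(county, age), sum))
    P <- with(evs, tapply(population, list(county, age), sum))
    D_all <- D_all[as.character(ids), age_groups()]
    D_card <- D_card[as.character(ids), age_groups()]
    P <- P[as.character(ids), age_groups()]
    units <- if (unit == "national") list(national = seq_along(ids))
    else stats::setNames(as.list(seq_along(ids)), as.character(ids))
    for (u in names(units)) {
      sel <- units[[u]]
      d_all <- colSums(D_all[sel, , drop = FALSE])
      d_card <- colSums(D_card[sel, , drop = FALSE])
      p <- colSums(P[sel, , drop = FALSE])
      e0_obs <- life_expectancy(d_all / p)
      av <- apply(arr[sel, , , drop = FALSE], c(2, 3), sum)  # age x draw
      over <- av > d_card
      if (any(over)) {
        clipped <- TRUE
        av <- pmin(av, d_card)
      }
      loss_r <- vapply(seq_len(R), function(r)
        life_expectancy(pmax(d_all - av[, r], 0) / p) - e0_obs, 0)
      rows[[paste(u, s)]] <- data.frame(
        unit = u, sex = s, e0_observed = e0_obs,
        e0_counterfactual = e0_obs + mean(loss_r),
        loss_mean = mean(loss_r),
        loss_lo = stats::quantile(loss_r, 0.025),
        loss_hi = stats::quantile(loss_r, 0.975))
      loss_draws[[paste(u, s)]] <- loss_r
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("le_loss", "data.frame"),
            draws = loss_draws, clipped = clipped,
            scenario = attribution$scenario$name)
}

#' @export
print.le_loss <- function(x, ...) {
  cat(sprintf("Life-expectancy loss under scenario '%s'\n",
              attr(x, "scenario")))
  df <- as.data.frame(x)
  if (nrow(df) <= 10) {
    print(cbind(df[1:2], round(df[-(1:2)], 4)), row.names = FALSE)
  } else {
    cat(sprintf("  %d unit-sex rows; loss range %.3f to %.3f years\n",
                nrow(df), min(df$loss_mean), max(df$loss_mean)))
  }
  if (isTRUE(attr(x, "clipped")))
    cat("  note: some draws clipped at the cardiorespiratory death count\n")
  invisible(x)
}
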