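## User-facing model fitting and S3 methods.

#' Control settings for \code{stpois()}
#'
#' @param fixed_prec Gaussian prior precision on the fixed effects
#'   (intercept, time slope, PM2.5 coefficient, covariate slopes).
#' @param hyper_a,hyper_b Gamma(\code{a}, \code{b}) prior on each
#'   random-effect precision (equivalently logGamma on the log precision).
#' @param rw1 Include the first-order random-walk year effect. Disabling
#'   it (together with \code{overdispersion}) gives a fixed-effects-only
#'   model comparable to maximum-likelihood Poisson regression.
#' @param overdispersion Include the iid county-year overdispersion term.
#' @param n_draws Number of posterior draws of the PM2.5 coefficient kept
#'   for attribution.
#' @param newton_maxit,newton_tol Inner-mode Newton iteration controls.
#' @param hyper_maxit,hyper_reltol Hyperparameter optimisation controls.
#' @return A list of class \code{stpois_control}.
#' @export
stpois_control <- function(fixed_prec = 0.001, hyper_a = 1,
                           hyper_b = 0.001, rw1 = TRUE,
                           overdispersion = TRUE, n_draws = 1000,
                           newton_maxit = 60, newton_tol = 1e-9,
                           hyper_maxit = 200, hyper_reltol = 1e-6) {
  structure(list(fixed_prec = fixed_prec, hyper_a = hyper_a,
                 hyper_b = hyper_b, rw1 = rw1,
                 overdispersion = overdispersion, n_draws = n_draws,
                 newton_maxit = newton_maxit, newton_tol = newton_tol,
                 hyper_maxit = hyper_maxit, hyper_reltol = hyper_reltol),
            class = "stpois_control")
}

#' Fit a Bayesian spatiotemporal Poisson mortality model
#'
#' Fits one of the four county-level models relating age- and sex-specific
#' cardiorespiratory death rates to annual PM2.5:
#' deaths ~ Poisson(rate x population), with
#' \code{log(rate) = alpha0 + beta0*year + nu_year [+ alpha_county
#' [+ beta_county*year]] + gamma*PM [+ theta'X] + eps}. The year is
#' centred at the panel mid-year; \code{nu} is a sum-to-zero,
#' orthogonal-to-year first-order random walk; county intercepts/slopes
#' follow an intrinsic CAR prior over the adjacency graph with
#' per-component sum-to-zero constraints; \code{eps} is iid Gaussian
#' overdispersion. Random-effect precisions carry Gamma(1, 0.001)
#' hyperpriors and are estimated by maximising their Laplace-approximate
#' marginal posterior; the latent field is then summarised by the
#' Gaussian approximation at the joint mode.
#'
#' @param panel A \code{county_panel}.
#' @param model Model name (see \code{model_spec()}) or a
#'   \code{model_spec}.
#' @param sex \code{"female"} or \code{"male"}.
#' @param age_group One of \code{age_groups()}.
#' @param control A \code{stpois_control()}.
#' @param seed Seed for the stored posterior draws of gamma.
#' @return An object of class \code{stpois} with components including
#'   \code{coefficients} (posterior means of the fixed effects),
#'   \code{vcov}, \code{summary_fixed}, \code{nu}, \code{alpha_county},
#'   \code{beta_county}, \code{precisions} (estimated random-effect
#'   precisions), \code{gamma_draws} and \code{converged}.
#' @examples
#' \donttest{
#' panel <- generate_panel(panel_config(n_counties = 20, seed = 1))
#' fit <- stpois(panel, "covariate", sex = "female", age_group = "75-79")
#' summary(fit)
#' rate_ratio(fit, delta_pm = 10)
#' }
#' @export
stpois <- function(panel, model = "covariate_county",
                   sex = c("female", "male"), age_group = "85+",
                   control = stpois_control(), seed = 1L) {
  sex <- match.arg(sex)
  design <- if (inherits(panel, "stpois_design")) panel
            else build_design(panel, model, sex = sex,
                              age_group = age_group)
  eng <- stpois_engine(design, control)
  lat <- eng$lat
  p <- lat$p_fix
  ix_fix <- seq_len(p)
  coefs <- stats::setNames(eng$z[ix_fix], lat$fixed_names)
  Vfix <- eng$V[ix_fix, ix_fix, drop = FALSE]
  dimnames(Vfix) <- list(lat$fixed_names, lat$fixed_names)

  qn <- function(m, s) cbind(mean = m, sd = s,
                             `2.5%` = m - 1.959964 * s, `50%` = m,
                             `97.5%` = m + 1.959964 * s)
  summary_fixed <- as.data.frame(qn(coefs, eng$sd[ix_fix]))

  at <- p
  nu <- alpha_c <- beta_c <- NULL
  for (i in seq_len(nrow(lat$blocks))[-1]) {
    b <- lat$blocks$block[i]; sz <- lat$blocks$size[i]
    ix <- at + seq_len(sz)
    if (b == "nu") {
      B <- lat$nu_basis
      mns <- drop(B %*% eng$z[ix])
      sds <- sqrt(pmax(rowSums((B %*% eng$V[ix, ix]) * B), 0))
      nu <- data.frame(year = design$years, mean = mns, sd = sds)
    } else {
      Vb <- lat$car$V
      mns <- drop(Vb %*% eng$z[ix])
      sds <- sqrt(pmax(rowSums((Vb %*% eng$V[ix, ix]) * Vb), 0))
      tab <- data.frame(county = design$county_ids, mean = mns, sd = sds)
      if (b == "alpha_c") alpha_c <- tab else beta_c <- tab
    }
    at <- at + sz
  }

  gamma_i <- match("gamma", lat$fixed_names)
  gamma_draws <- with_stream(as.integer(seed),
    stats::rnorm(control$n_draws, coefs[gamma_i], eng$sd[gamma_i]))

  structure(list(
    call = match.call(),
    spec = design$spec, sex = sex, age_group = design$age_group,
    coefficients = coefs, vcov = Vfix,
    summary_fixed = summary_fixed,
    nu = nu, alpha_county = alpha_c, beta_county = beta_c,
    overdispersion = if (control$overdispersion)
      data.frame(county = design$county, year = design$year,
                 mean = eng$eps) else NULL,
    precisions = vapply(eng$ltau, exp, 0),
    gamma_draws = gamma_draws,
    fitted_rates = eng$mu / design$population,
    data = list(y = design$y, population = design$population,
                county = design$county, year = design$year,
                pm = design$pm),
    lml = eng$lml, converged = eng$converged,
    newton_iter = eng$newton_iter,
    control = control, seed = as.integer(seed)), class = "stpois")
}

#' @export
print.stpois <- function(x, ...) {
  g <- x$summary_fixed["gamma", ]
  cat(sprintf("Spatiotemporal Poisson fit ('%s'), %s %s\n",
              x$spec$name, x$sex, x$age_group))
  cat(sprintf("  gamma (log RR per ug/m3): %.5f (95%% CrI %.5f, %.5f)\n",
              g$mean, g$`2.5%`, g$`97.5%`))
  cat(sprintf("  RR per 10 ug/m3: %.3f\n", exp(10 * g$mean)))
  if (!x$converged) cat("  WARNING: fit flagged as not converged\n")
  invisible(x)
}

#' @export
summary.stpois <- function(object, ...) {
  out <- list(fixed = object$summary_fixed,
              precisions = object$precisions,
              spec = object$spec, sex = object$sex,
              age_group = object$age_group,
              converged = object$converged)
  class(out) <- "summary.stpois"
  out
}

#' @export
print.summary.stpois <- function(x, ...) {
  cat(sprintf("Model '%s', %s %s%s\n", x$spec$name, x$sex, x$age_group,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  cat("Fixed effects (posterior mean, sd, 95% credible interval):\n")
  print(round(x$fixed, 5))
  if (length(x$precisions)) {
    cat("Random-effect precisions (marginal posterior mode):\n")
    print(signif(x$precisions, 4))
  }
  invisible(x)
}

#' @export
coef.stpois <- function(object, ...) object$coefficients

#' @export
vcov.stpois <- function(object, ...) object$vcov

#' @export
fitted.stpois <- function(object, ...)
  object$fitted_rates * object$data$population

#' @export
residuals.stpois <- function(object, type = c("pearson", "deviance"), ...) {
  type <- match.arg(type)
  y <- object$data$y; mu <- fitted(object)
  if (type == "pearson") return((y - mu) / sqrt(mu))
  sign(y - mu) * sqrt(2 * (ifelse(y > 0, y * log(y / mu), 0) - (y - mu)))
}

#' @export
simulate.stpois <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  mu <- fitted(object)
  as.data.frame(replicate(nsim, stats::rpois(length(mu), mu)))
}

#' Posterior rate ratio for a PM2.5 increment
#'
#' Summarises \code{exp(gamma * delta_pm)} over the stored posterior
#' draws of the PM2.5 coefficient; \code{delta_pm = 1} is the per-ug/m3
#' reporting unit and \code{delta_pm = 10} the per-10-ug/m3 unit.
#'
#' @param fit A \code{stpois} fit.
#' @param delta_pm PM2.5 increment in ug/m3.
#' @return Named vector: mean, sd, 2.5/50/97.5 percentiles.
#' @export
rate_ratio <- function(fit, delta_pm = 1) {
  stopifnot(inherits(fit, "stpois"))
  rr <- exp(fit$gamma_draws * delta_pm)
  c(mean = mean(rr), sd = stats::sd(rr),
    stats::quantile(rr, c(0.025, 0.5, 0.975)))
}

#' Fit all sex-age strata of one model
#'
#' Fans the chosen model out over the 36 (or a chosen subset of)
#' sex-by-age strata, fitting each independently.
#'
#' @param panel A \code{county_panel}.
#' @param model Model name or \code{model_spec}.
#' @param sexes,ages Strata to fit (defaults: all).
#' @param control A \code{stpois_control()}.
#' @param seed Base seed; each stratum's draw seed is derived from it.
#' @param verbose Print progress.
#' @return A list of \code{stpois} fits of class \code{stpois_strata},
#'   named \code{"<sex>.<age>"}.
#' @export
fit_strata <- function(panel, model = "covariate_county",
                       sexes = c("female", "male"), ages = age_groups(),
                       control = stpois_control(), seed = 1L,
                       verbose = FALSE) {
  fits <- list()
  for (s in sexes) for (a in ages) {
    if (verbose) message("fitting ", s, " ", a)
    key <- paste(s, a, sep = ".")
    fits[[key]] <- stpois(panel, model, sex = s, age_group = a,
                          control = control,
                          seed = stream_seed(seed, 0, match(s, c("female",
                                                                 "male")),
                                             match(a, age_groups())))
  }
  structure(fits, class = "stpois_strata")
}

#' @export
print.stpois_strata <- function(x, ...) {
  cat(sprintf("Fits for %d sex-age strata (model '%s')\n",
              length(x), x[[1]]$spec$name))
  bad <- names(x)[!vapply(x, `[[`, TRUE, "converged")]
  if (length(bad))
    cat("  not converged:", paste(bad, collapse = ", "), "\n")
  invisible(x)
}
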