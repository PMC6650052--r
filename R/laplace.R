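## Latent-Gaussian engine for the spatiotemporal Poisson models.
##
## The linear predictor is eta = A z + eps, with z the structured latent
## vector (fixed effects; RW1 year effects in a sum-to-zero,
## orthogonal-to-year spectral basis; intrinsic-CAR county intercepts and
## slopes in the positive-eigenvalue basis of the graph Laplacian, which
## enforces per-component sum-to-zero) and eps iid N(0, 1/tau_eps)
## overdispersion, one per county-year. Poisson counts y ~ Pois(N exp(eta)).
##
## Inference: Gaussian (Laplace) approximation at the joint posterior
## mode; the iid eps block is eliminated analytically so every Newton
## step solves a dense m x m system in the structured block only.
## Random-effect precisions get Gamma(1, 0.001) priors (equivalently
## logGamma(1, 0.001) on the log precision) and are estimated by
## maximising the Laplace approximation to their marginal posterior.

## RW1 structure matrix (first-difference penalty) for T time points.
rw1_structure <- function(Tn) {
  D1 <- diff(diag(Tn))
  crossprod(D1)
}

## Orthonormal basis of the complement of span{1, t}: the RW1 effects live
## here, separating the nonlinear trend from intercept and linear slope.
rw1_basis <- function(t_unique) {
  Tn <- length(t_unique)
  qr.Q(qr(cbind(1, t_unique)), complete = TRUE)[, -(1:2), drop = FALSE]
}

## Graph Laplacian (D - W) of the county adjacency among `ids`.
graph_laplacian <- function(ids, adjacency) {
  C <- length(ids)
  W <- matrix(0, C, C)
  if (nrow(adjacency)) {
    f <- match(adjacency$from, ids); t <- match(adjacency$to, ids)
    keep <- !is.na(f) & !is.na(t)
    W[cbind(f[keep], t[keep])] <- 1
    W[cbind(t[keep], f[keep])] <- 1
  }
  diag(rowSums(W), C) - W
}

## Spectral basis of the intrinsic CAR field: positive-eigenvalue
## eigenvectors of the Laplacian (per-component sum-to-zero), with iid
## coordinates appended for isolated counties (exchangeable Gaussian).
car_basis <- function(ids, adjacency) {
  L <- graph_laplacian(ids, adjacency)
  C <- length(ids)
  islands <- which(diag(L) == 0)
  eg <- eigen(L, symmetric = TRUE)
  pos <- eg$values > 1e-8 * max(eg$values, 1)
  V <- eg$vectors[, pos, drop = FALSE]
  lam <- eg$values[pos]
  if (length(islands)) {
    E <- matrix(0, C, length(islands))
    E[cbind(islands, seq_along(islands))] <- 1
    V <- cbind(V, E)
    lam <- c(lam, rep(1, length(islands)))
  }
  list(V = V, lambda = lam, islands = islands)
}

## Assemble the structured design matrix and prior metadata.
build_latent <- function(design, control) {
  spec <- design$spec
  Tn <- length(design$years)
  terms <- list()

  Ffix <- cbind(alpha0 = 1, beta0 = design$t, gamma = design$pm)
  if (spec$include_covariates) {
    Xc <- scale(design$X, center = TRUE, scale = FALSE)
    colnames(Xc) <- paste0("theta_", covariate_names())
    Ffix <- cbind(Ffix, Xc)
  }
  p_fix <- ncol(Ffix)
  A <- Ffix
  blocks <- data.frame(block = "fixed", size = p_fix)

  nu_basis <- NULL; K_nu <- NULL
  if (control$rw1 && Tn >= 3) {
    tu <- sort(unique(design$t))
    nu_basis <- rw1_basis(tu)
    K_nu <- crossprod(nu_basis, rw1_structure(Tn) %*% nu_basis)
    A <- cbind(A, nu_basis[design$year_index, , drop = FALSE])
    blocks <- rbind(blocks, data.frame(block = "nu", size = ncol(nu_basis)))
  }

  car <- NULL
  if (spec$include_county_intercepts) {
    car <- car_basis(design$county_ids, design$adjacency)
    A <- cbind(A, car$V[design$county_index, , drop = FALSE])
    blocks <- rbind(blocks, data.frame(block = "alpha_c",
                                       size = ncol(car$V)))
  }
  if (spec$include_county_slopes) {
    if (is.null(car)) car <- car_basis(design$county_ids, design$adjacency)
    A <- cbind(A, car$V[design$county_index, , drop = FALSE] * design$t)
    blocks <- rbind(blocks, data.frame(block = "beta_c",
                                       size = ncol(car$V)))
  }

  hyper <- c(if (control$rw1 && Tn >= 3) "nu",
             if (spec$include_county_intercepts) "alpha_c",
             if (spec$include_county_slopes) "beta_c",
             if (control$overdispersion) "eps")

  list(A = A, p_fix = p_fix, blocks = blocks, hyper = hyper,
       nu_basis = nu_basis, K_nu = K_nu, car = car,
       fixed_names = colnames(Ffix))
}

## Prior precision of the structured block at given log-precisions, with
## its log determinant.
prior_precision <- function(lat, ltau, control) {
  m <- ncol(lat$A)
  Q <- diag(rep(control$fixed_prec, m))
  logdet <- lat$p_fix * log(control$fixed_prec)
  at <- lat$p_fix
  for (i in seq_len(nrow(lat$blocks))[-1]) {
    b <- lat$blocks$block[i]; sz <- lat$blocks$size[i]
    ix <- at + seq_len(sz)
    tau <- exp(ltau[[b]])
    if (b == "nu") {
      Q[ix, ix] <- tau * lat$K_nu
      logdet <- logdet + sz * ltau[[b]] +
        determinant(lat$K_nu, logarithm = TRUE)$modulus
    } else {
      Q[ix, ix] <- diag(tau * lat$car$lambda, sz)
      logdet <- logdet + sz * ltau[[b]] + sum(log(lat$car$lambda))
    }
    at <- at + sz
  }
  list(Q = Q, logdet = as.numeric(logdet))
}

## Joint Newton optimisation of (z, eps) at fixed hyperparameters, with
## analytic elimination of eps. Returns mode, Cholesky of the structured
## conditional precision, and the Laplace marginal log-posterior.
newton_mode <- function(y, N, lat, Qp, tau_e, control, z0, e0) {
  A <- lat$A
  n <- length(y); m <- ncol(A)
  overdisp <- !is.null(tau_e)
  z <- if (is.null(z0)) rep(0, m) else z0
  eps <- if (is.null(e0) || !overdisp) rep(0, n) else e0
  logN <- log(N)

  obj <- function(z, eps) {
    eta <- drop(A %*% z) + eps
    mu <- N * exp(pmin(eta, 40))
    f <- sum(mu) - sum(y * eta) + 0.5 * sum(z * (Qp$Q %*% z))
    if (overdisp) f <- f + 0.5 * tau_e * sum(eps^2)
    f
  }

  f <- obj(z, eps)
  ch <- NULL; Dv <- NULL
  for (it in seq_len(control$newton_maxit)) {
    eta <- drop(A %*% z) + eps
    mu <- N * exp(pmin(eta, 40))
    w <- mu
    r <- y - mu
    gz <- drop(Qp$Q %*% z) - drop(crossprod(A, r))
    if (overdisp) {
      ge <- tau_e * eps - r
      Dv <- tau_e + w
      wt <- w * tau_e / Dv
      rhs <- -gz + drop(crossprod(A, (w / Dv) * ge))
    } else {
      ge <- numeric(0)
      wt <- w
      rhs <- -gz
    }
    M <- Qp$Q + crossprod(A * sqrt(wt))
    ch <- chol(M)
    dz <- backsolve(ch, backsolve(ch, rhs, transpose = TRUE))
    de <- if (overdisp) (-ge - w * drop(A %*% dz)) / Dv else numeric(n)

    step <- 1
    repeat {
      f_new <- obj(z + step * dz, eps + step * de)
      if (is.finite(f_new) && f_new <= f + 1e-12 * abs(f)) break
      step <- step / 2
      if (step < 1e-8) break
    }
    z_new <- z + step * dz; e_new <- eps + step * de
    done <- abs(f - f_new) < control$newton_tol * (abs(f) + 1) ||
      max(abs(c(gz, ge))) < 1e-7 * (1 + max(abs(y)))
    z <- z_new; eps <- e_new; f <- f_new
    if (done) break
  }

  eta <- drop(A %*% z) + eps
  mu <- N * exp(pmin(eta, 40))
  ## recompute conditional precision at the mode
  w <- mu
  if (overdisp) {
    Dv <- tau_e + w
    wt <- w * tau_e / Dv
  } else wt <- w
  M <- Qp$Q + crossprod(A * sqrt(wt))
  ch <- chol(M)

  ll <- sum(y * (logN + eta) - mu - lgamma(y + 1))
  lp_z <- 0.5 * Qp$logdet - 0.5 * m * log(2 * pi) -
    0.5 * sum(z * (Qp$Q %*% z))
  d <- m
  lp_e <- 0
  logdetH <- 2 * sum(log(diag(ch)))
  if (overdisp) {
    lp_e <- 0.5 * n * log(tau_e) - 0.5 * n * log(2 * pi) -
      0.5 * tau_e * sum(eps^2)
    logdetH <- logdetH + sum(log(Dv))
    d <- d + n
  }
  lml <- ll + lp_z + lp_e + 0.5 * d * log(2 * pi) - 0.5 * logdetH

  list(z = z, eps = eps, chol = ch, lml = lml, iter = it,
       converged = it < control$newton_maxit || done,
       mu = mu, eta = eta)
}

## Empirical-Bayes estimation of the log precisions, then the Gaussian
## approximation at the mode.
stpois_engine <- function(design, control) {
  y <- design$y; N <- design$population
  if (stats::sd(design$pm) < 1e-10)
    stop("degenerate design: PM2.5 has no variation across county-years")
  lat <- build_latent(design, control)
  hyper <- lat$hyper
  nh <- length(hyper)

  state <- new.env()
  state$z <- NULL; state$eps <- NULL

  eval_lml <- function(lt) {
    names(lt) <- hyper
    if (any(lt < -8) || any(lt > 18)) return(-1e10)
    ltau <- as.list(lt)
    tau_e <- if ("eps" %in% hyper) exp(ltau$eps) else NULL
    Qp <- prior_precision(lat, ltau, control)
    fit <- newton_mode(y, N, lat, Qp, tau_e, control, state$z, state$eps)
    state$z <- fit$z; state$eps <- fit$eps
    ## Gamma(1, 0.001) prior on each precision, as a density in log tau
    lhyp <- sum(control$hyper_a * lt - control$hyper_b * exp(lt))
    fit$lml + lhyp
  }

  init <- stats::setNames(rep(4, nh), hyper)
  if ("eps" %in% hyper) init["eps"] <- 6
  if (nh == 0) {
    ltau_hat <- numeric(0)
    opt_conv <- 0L
  } else if (nh == 1) {
    op <- stats::optimize(function(v) -eval_lml(v), interval = c(-4, 14))
    ltau_hat <- stats::setNames(op$minimum, hyper)
    opt_conv <- 0L
  } else {
    op <- stats::optim(init, function(v) -eval_lml(v),
                       method = "Nelder-Mead",
                       control = list(maxit = control$hyper_maxit,
                                      reltol = control$hyper_reltol))
    ltau_hat <- op$par
    opt_conv <- op$convergence
  }

  ltau <- as.list(stats::setNames(as.numeric(ltau_hat), hyper))
  tau_e <- if ("eps" %in% hyper) exp(ltau$eps) else NULL
  Qp <- prior_precision(lat, ltau, control)
  fit <- newton_mode(y, N, lat, Qp, tau_e, control, state$z, state$eps)

  V <- chol2inv(fit$chol)
  sds <- sqrt(pmax(diag(V), 0))

  list(lat = lat, z = fit$z, eps = fit$eps, V = V, sd = sds,
       ltau = ltau, lml = fit$lml,
       converged = fit$converged && opt_conv == 0L,
       newton_iter = fit$iter, mu = fit$mu, eta = fit$eta,
       tau_e = tau_e)
}
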