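## Comparison models: AM (no random effects), AMM (random intercept + slope),
## FRI (functional random intercept, no covariates).

#' Additive model with no random effects
#'
#' Same mean structure as [fit_fcr()] but with independent errors,
#' `V_i = sigma2 I`. The residual variance is estimated by the residual mean
#' square with an effective-degrees-of-freedom correction; the sandwich
#' covariance is computed under the (working) independence assumption.
#'
#' @inheritParams fit_fcr
#' @return An `fcr_fit` with `model = "am"` and `Gamma = 0`.
#' @export
fit_am <- function(data, id = "id", time = "time", outcome = "y",
                   invariant = character(), varying = character(),
                   basis = NULL, n_interior = 6L, o = 2L,
                   selector = c("reml", "gcv"), covariate_models = NULL) {
  selector <- match.arg(selector)
  if (is.null(basis))
    basis <- fcr_basis(data[[time]], n_interior = n_interior)
  c <- basis$c
  cov_models <- covariate_models %||% list()
  for (v in varying) {
    if (is.null(cov_models[[v]])) {
      sub <- data[!is.na(data[[v]]), c(id, time, v)]
      names(sub) <- c("id", "time", "value")
      cov_models[[v]] <- fpca_sparse(sub, basis)
    }
  }
  blocks <- assemble_design(data, basis, id, time, outcome,
                            invariant, varying, cov_models)
  nb <- 1L + length(invariant) + length(varying)
  st <- pgls_stats(blocks, Gamma = NULL, sigma2 = 1)
  lam <- select_smoothing_stats(st, c, o, selector, nb)
  f0 <- pgls_from_stats(st, lam, c, o)
  theta <- f0$theta
  rss <- st$q - 2 * sum(theta * st$u) +
    drop(crossprod(theta, st$S %*% theta))
  edf <- sum(block_edf(st, lam, c, o))
  sigma2 <- rss / max(st$n - edf, 1)
  # rescale so theta is unchanged under V = sigma2 I
  st2 <- lapply(st, identity)
  st2$S <- st$S / sigma2; st2$u <- st$u / sigma2; st2$q <- st$q / sigma2
  f1 <- pgls_from_stats(st2, lam / sigma2, c, o)

  terms <- c("(Intercept)", invariant, varying)
  structure(
    list(model = "am", basis = basis, theta = f1$theta, lambdas = lam,
         cov_theta = f1$cov_theta, cov_bayes = f1$cov_bayes,
         Gamma = matrix(0, c, c), sigma2 = sigma2,
         covariate_models = cov_models, terms = terms,
         invariant = invariant, varying = varying, selector = selector,
         o = o, N = length(blocks), t_max = max(data[[time]]),
         columns = list(id = id, time = time, outcome = outcome)),
    class = "fcr_fit"
  )
}

#' Functional random intercept model (no covariates)
#'
#' [fit_fcr()] with an empty covariate list: outcome modelled by a smooth
#' population mean plus the subject-specific random function.
#'
#' @inheritParams fit_fcr
#' @export
fit_fri <- function(data, id = "id", time = "time", outcome = "y",
                    basis = NULL, n_interior = 6L, n_interior_cov = NULL,
                    o = 2L, selector = c("reml", "gcv"), cycles = 1L) {
  fit_fcr(data, id = id, time = time, outcome = outcome,
          invariant = character(), varying = character(), basis = basis,
          n_interior = n_interior, n_interior_cov = n_interior_cov, o = o,
          selector = selector, cycles = cycles)
}

# ---- additive mixed model (random intercept + slope) ---------------------

# whitened statistics under V_i = Z_i Psi Z_i' + sigma2 I, Z_i = [1, t_i];
# also accumulates sum log|V_i| for the REML objective
amm_stats <- function(blocks, Psi, sigma2) {
  d <- ncol(blocks[[1]]$X)
  S <- matrix(0, d, d); u <- numeric(d); q <- 0; n <- 0L; ld <- 0
  for (bl in blocks) {
    Zi <- cbind(1, bl$t)
    V <- Zi %*% Psi %*% t(Zi) + sigma2 * diag(bl$m)
    R <- chol_jitter(V)
    Xw <- backsolve(R, bl$X, transpose = TRUE)
    yw <- backsolve(R, bl$y, transpose = TRUE)
    S <- S + crossprod(Xw)
    u <- u + drop(crossprod(Xw, yw))
    q <- q + sum(yw^2)
    n <- n + bl$m
    ld <- ld + 2 * sum(log(diag(R)))
  }
  list(S = S, u = u, q = q, n = n, N = length(blocks), d = d, logdetV = ld)
}

# penalized REML objective for the AMM variance components (lambda fixed):
#   sum_i log|V_i| + log|S + N P| + (q - theta' u)
amm_reml <- function(st, lambdas, c, o) {
  M <- st$S + st$N * block_penalty(lambdas, c, o)
  R <- tryCatch(chol(M), error = function(e) NULL)
  if (is.null(R)) return(Inf)
  theta <- backsolve(R, backsolve(R, st$u, transpose = TRUE))
  st$logdetV + 2 * sum(log(diag(R))) + (st$q - sum(theta * st$u))
}

# method-of-moments starting values: regress residual cross-products on the
# random intercept/slope structure
amm_moments <- function(blocks, theta) {
  Xr <- NULL; wr <- NULL; dsq <- numeric(0); dt <- numeric(0)
  for (bl in blocks) {
    r <- bl$y - drop(bl$X %*% theta)
    m <- bl$m
    dsq <- c(dsq, r^2); dt <- c(dt, bl$t)
    if (m < 2L) next
    pr <- which(upper.tri(matrix(0, m, m)), arr.ind = TRUE)
    tj <- bl$t[pr[, 1]]; tk <- bl$t[pr[, 2]]
    Xr <- rbind(Xr, cbind(1, tj + tk, tj * tk))
    wr <- c(wr, r[pr[, 1]] * r[pr[, 2]])
  }
  cf <- tryCatch(stats::lm.fit(Xr, wr)$coefficients,
                 error = function(e) c(stats::var(wr), 0, 0))
  cf[is.na(cf)] <- 0
  Psi <- matrix(c(cf[1], cf[2], cf[2], cf[3]), 2, 2)
  e <- eigen(Psi, symmetric = TRUE)
  Psi <- e$vectors %*% (pmax(e$values, 1e-6) * t(e$vectors))
  fitted_diag <- cbind(1, 2 * dt, dt^2) %*% c(Psi[1, 1], Psi[1, 2], Psi[2, 2])
  sigma2 <- max(mean(dsq - fitted_diag), 1e-4 * stats::var(dsq)^0.5, 1e-8)
  list(Psi = Psi, sigma2 = sigma2)
}

par_to_vc <- function(par) {
  L <- matrix(c(exp(par[2]), par[3], 0, exp(par[4])), 2, 2)
  list(sigma2 = exp(par[1]), Psi = L %*% t(L))
}

#' Additive mixed model with random intercept and slope
#'
#' Same penalized mean structure as [fit_fcr()], but subject deviation
#' modelled as `b_0i + b_1i t` with `(b_0i, b_1i)` bivariate normal with
#' unstructured covariance `Psi`. Variance components are estimated by direct
#' REML on the profiled likelihood (Nelder-Mead over a log-Cholesky
#' parameterization, started from method-of-moments values), and fixed effects
#' by penalized GLS under the fitted `V_i`.
#'
#' @inheritParams fit_fcr
#' @return An object of class `amm_fit`.
#' @export
fit_amm <- function(data, id = "id", time = "time", outcome = "y",
                    invariant = character(), varying = character(),
                    basis = NULL, n_interior = 6L, o = 2L,
                    selector = c("reml", "gcv"), covariate_models = NULL) {
  selector <- match.arg(selector)
  if (is.null(basis))
    basis <- fcr_basis(data[[time]], n_interior = n_interior)
  c <- basis$c
  cov_models <- covariate_models %||% list()
  for (v in varying) {
    if (is.null(cov_models[[v]])) {
      sub <- data[!is.na(data[[v]]), c(id, time, v)]
      names(sub) <- c("id", "time", "value")
      cov_models[[v]] <- fpca_sparse(sub, basis)
    }
  }
  blocks <- assemble_design(data, basis, id, time, outcome,
                            invariant, varying, cov_models)
  if (!any(vapply(blocks, function(b) b$m >= 2L, logical(1))))
    stop("need at least one subject with two or more visits")
  nb <- 1L + length(invariant) + length(varying)

  st0 <- pgls_stats(blocks, Gamma = NULL, sigma2 = 1)
  lam <- select_smoothing_stats(st0, c, o, selector, nb)
  f0 <- pgls_from_stats(st0, lam, c, o)
  start <- amm_moments(blocks, f0$theta)

  L0 <- tryCatch(t(chol(start$Psi + 1e-8 * diag(2))),
                 error = function(e) diag(2) * 1e-3)
  par0 <- c(log(start$sigma2), log(max(L0[1, 1], 1e-6)), L0[2, 1],
            log(max(L0[2, 2], 1e-6)))
  obj <- function(par) {
    vc <- par_to_vc(par)
    st <- amm_stats(blocks, vc$Psi, vc$sigma2)
    amm_reml(st, lam, c, o)
  }
  opt <- stats::optim(par0, obj, method = "Nelder-Mead",
                      control = list(maxit = 300, reltol = 1e-9))
  vc <- par_to_vc(opt$par)
  Psi <- (vc$Psi + t(vc$Psi)) / 2
  sigma2 <- vc$sigma2

  st1 <- amm_stats(blocks, Psi, sigma2)
  lam <- select_smoothing_stats(st1, c, o, selector, nb)
  f1 <- pgls_from_stats(st1, lam, c, o)

  terms <- c("(Intercept)", invariant, varying)
  structure(
    list(model = "amm", basis = basis, theta = f1$theta, lambdas = lam,
         cov_theta = f1$cov_theta, cov_bayes = f1$cov_bayes,
         Psi = Psi, sigma2 = sigma2,
         reml = opt$value, covariate_models = cov_models, terms = terms,
         invariant = invariant, varying = varying, selector = selector,
         o = o, N = length(blocks), t_max = max(data[[time]]),
         columns = list(id = id, time = time, outcome = outcome)),
    class = "amm_fit"
  )
}

#' @export
print.amm_fit <- function(x, ...) {
  cat("Additive mixed model (random intercept + slope)\n")
  cat("  subjects:", x$N, " sigma2 =", format(x$sigma2, digits = 4), "\n")
  cat("  Psi:\n"); print(signif(x$Psi, 4))
  invisible(x)
}

#' @export
predict_trajectory.amm_fit <- function(fit, history, t_grid, cutoff = NULL,
                                       invariant_values = NULL,
                                       future_covariates = NULL) {
  check_horizon(fit, t_grid)
  h <- prepare_history(fit, history, cutoff)
  Zg <- covariate_values_at(fit, h$history, t_grid, h$cutoff,
                            invariant_values, future_covariates)
  fixed_g <- fixed_part(fit, t_grid, Zg)
  Zt <- cbind(1, t_grid)
  prior_var <- rowSums((Zt %*% fit$Psi) * Zt)
  m <- length(h$t_obs)
  if (m == 0L) {
    b <- c(0, 0)
    var_t <- prior_var + fit$sigma2
    yhat <- fixed_g
  } else {
    Zh <- covariate_values_at(fit, h$history, h$t_obs, h$cutoff,
                              invariant_values, future_covariates)
    fixed_h <- fixed_part(fit, h$t_obs, Zh)
    Zs <- cbind(1, h$t_obs)
    K <- Zs %*% fit$Psi %*% t(Zs) + fit$sigma2 * diag(m)
    R <- chol_jitter(K)
    resid <- h$y_obs - fixed_h
    PZ <- fit$Psi %*% t(Zs)
    alpha <- backsolve(R, backsolve(R, resid, transpose = TRUE))
    b <- drop(PZ %*% alpha)
    W <- backsolve(R, t(Zt %*% PZ), transpose = TRUE)
    var_t <- pmax(prior_var - colSums(W^2), 0) + fit$sigma2
    yhat <- fixed_g + drop(Zt %*% b)
  }
  sd_t <- sqrt(var_t)
  out <- data.frame(t = t_grid, y_hat = yhat, sd = sd_t,
                    lo95 = yhat - 2 * sd_t, hi95 = yhat + 2 * sd_t)
  structure(out, u_tilde = b, cutoff = h$cutoff, t_max = fit$t_max,
            class = c("fcr_prediction", "data.frame"))
}
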