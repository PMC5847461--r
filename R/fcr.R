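## Functional concurrent regression by penalized generalized least squares.
##
## Model: Y_ij = f_0(t_ij) + sum_p z_p,ij f_p(t_ij) + b_i(t_ij) + eps_ij,
## with every f_p expanded in a shared B-spline basis (coefficients theta_p,
## difference penalty lambda_p D'D) and the functional random intercept b_i
## expanded in the same basis with coefficient covariance Gamma, so that
## V_i = B_i Gamma B_i' + sigma2 I.

# ---- design assembly ----------------------------------------------------

#' Assemble per-subject design blocks for the concurrent model
#'
#' Builds, for every subject, the stacked design
#' `X_i = [B_i, diag(z_1i) B_i, ..., diag(z_Pi) B_i]` where `B_i` holds the
#' basis evaluations at the subject's visit times. Time-invariant covariates
#' are broadcast across visits; time-varying covariates are replaced by their
#' BLUP reconstruction from the fitted covariate model at the outcome visit
#' times.
#'
#' @param data Long-format data frame, one row per subject-visit.
#' @param basis An [fcr_basis()].
#' @param id,time,outcome Column names.
#' @param invariant,varying Covariate column names.
#' @param covariate_models Named list of `fpca_model`s, one per varying
#'   covariate.
#' @return List of per-subject blocks (`id`, `t`, `y`, `B`, `Z`, `X`, `m`).
#' @export
assemble_design <- function(data, basis, id = "id", time = "time",
                            outcome = "y", invariant = character(),
                            varying = character(),
                            covariate_models = list()) {
  needed <- c(id, time, outcome, invariant, varying)
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols) > 0)
    stop("missing columns in data: ", paste(missing_cols, collapse = ", "))
  for (v in varying)
    if (is.null(covariate_models[[v]]))
      stop("no covariate model supplied for time-varying covariate '", v, "'")
  ord <- order(data[[id]], data[[time]])
  data <- data[ord, , drop = FALSE]
  idx <- split(seq_len(nrow(data)), data[[id]])
  P <- length(invariant) + length(varying)
  lapply(names(idx), function(sid) {
    i <- idx[[sid]]
    t_i <- as.numeric(data[[time]][i])
    y_i <- as.numeric(data[[outcome]][i])
    B <- eval_basis(basis, t_i)
    m <- length(t_i)
    Z <- matrix(0, m, P)
    p <- 0L
    for (v in invariant) {
      p <- p + 1L
      zv <- as.numeric(data[[v]][i])
      if (anyNA(zv)) stop("missing values in time-invariant covariate '", v, "'")
      Z[, p] <- zv
    }
    for (v in varying) {
      p <- p + 1L
      obs <- as.numeric(data[[v]][i])
      keep <- !is.na(obs)
      bl <- blup_curve(covariate_models[[v]], t_i[keep], obs[keep], t_i)
      Z[, p] <- bl$mean
    }
    X <- B
    if (P > 0)
      for (p in seq_len(P)) X <- cbind(X, Z[, p] * B)
    list(id = sid, t = t_i, y = y_i, B = B, Z = Z, X = X, m = m)
  })
}

# ---- penalized GLS ------------------------------------------------------

# Cholesky of V with escalating jitter; V_i = B Gamma B' + sigma2 I.
chol_jitter <- function(V) {
  m <- nrow(V)
  R <- tryCatch(chol(V), error = function(e) NULL)
  jit <- 1e-8 * max(sum(diag(V)) / m, 1)
  tries <- 0L
  while (is.null(R) && tries < 6L) {
    R <- tryCatch(chol(V + jit * diag(m)), error = function(e) NULL)
    jit <- jit * 100
    tries <- tries + 1L
  }
  if (is.null(R)) stop("covariance matrix V_i not positive definite")
  R
}

# Accumulate the whitened sufficient statistics
# S = sum X'V^-1 X, u = sum X'V^-1 y, q = sum y'V^-1 y, n = total rows.
pgls_stats <- function(blocks, Gamma = NULL, sigma2 = 1) {
  d <- ncol(blocks[[1]]$X)
  S <- matrix(0, d, d); u <- numeric(d); q <- 0; n <- 0L
  for (bl in blocks) {
    if (is.null(Gamma)) {
      Xw <- bl$X / sqrt(sigma2)
      yw <- bl$y / sqrt(sigma2)
    } else {
      # Bc: random-intercept basis evaluations (defaults to the fixed basis)
      Br <- bl$Bc %||% bl$B
      V <- Br %*% Gamma %*% t(Br) + sigma2 * diag(bl$m)
      R <- chol_jitter(V)
      Xw <- backsolve(R, bl$X, transpose = TRUE)
      yw <- backsolve(R, bl$y, transpose = TRUE)
    }
    S <- S + crossprod(Xw)
    u <- u + drop(crossprod(Xw, yw))
    q <- q + sum(yw^2)
    n <- n + bl$m
  }
  list(S = S, u = u, q = q, n = n, N = length(blocks), d = d)
}

block_penalty <- function(lambdas, c, o = 2L) {
  P1 <- difference_penalty(c, o)$matrix
  nb <- length(lambdas)
  P <- matrix(0, nb * c, nb * c)
  for (p in seq_len(nb)) {
    ix <- ((p - 1L) * c + 1L):(p * c)
    P[ix, ix] <- lambdas[p] * P1
  }
  P
}

#' Penalized generalized least squares for the concurrent model
#'
#' Solves
#' `theta_hat = (N^-1 sum_i X_i' V_i^-1 X_i + P)^-1 N^-1 sum_i X_i' V_i^-1 y_i`
#' with `P = blockdiag(lambda_p D'D)` and returns the sandwich covariance
#' `(A + P)^-1 (A / N) (A + P)^-1` where `A = N^-1 sum_i X_i' V_i^-1 X_i`.
#'
#' @param blocks Design blocks from [assemble_design()].
#' @param Gamma Random-intercept coefficient covariance (`NULL` for V = sigma2 I).
#' @param sigma2 Residual variance.
#' @param lambdas Per-block smoothing parameters (length P+1).
#' @param c Number of basis functions per block.
#' @param o Difference-penalty order.
#' @return List with `theta`, `cov_theta`, and the whitened statistics.
#' @export
pgls_solve <- function(blocks, Gamma = NULL, sigma2 = 1, lambdas, c, o = 2L) {
  st <- pgls_stats(blocks, Gamma, sigma2)
  pgls_from_stats(st, lambdas, c, o)
}

pgls_from_stats <- function(st, lambdas, c, o = 2L) {
  if (length(lambdas) * c != st$d)
    stop("lambdas/basis dimension mismatch with design")
  A <- st$S / st$N
  M <- A + block_penalty(lambdas, c, o)
  R <- tryCatch(chol(M), error = function(e) {
    blk <- "penalized information matrix"
    stop("rank-deficient ", blk, "; increase data or penalty")
  })
  Minv_u <- backsolve(R, backsolve(R, st$u / st$N, transpose = TRUE))
  Minv <- chol2inv(R)
  cov_theta <- Minv %*% (A / st$N) %*% Minv
  # model-based (Bayesian) covariance (A + P)^-1 / N: accounts for
  # penalty-induced bias and is what penalized-spline confidence bands use
  list(theta = drop(Minv_u), cov_theta = (cov_theta + t(cov_theta)) / 2,
       cov_bayes = (Minv + t(Minv)) / (2 * st$N),
       stats = st, lambdas = lambdas)
}

# ---- smoothing-parameter selection --------------------------------------

# REML criterion (scale profiled out) for the penalized regression with
# whitened statistics; S_lam = N * blockdiag(lambda_p D'D).
#   crit = (n - M0) log(RSS_pen) + log|S + S_lam| - sum_p (c - o) log(N lambda_p)
# GCV uses n RSS / (n - edf)^2.
selection_criterion <- function(st, lambdas, c, o, selector = "reml") {
  Slam <- st$N * block_penalty(lambdas, c, o)
  M <- st$S + Slam
  R <- tryCatch(chol(M), error = function(e) NULL)
  if (is.null(R)) return(Inf)
  theta <- backsolve(R, backsolve(R, st$u, transpose = TRUE))
  if (selector == "reml") {
    rss_pen <- max(st$q - sum(theta * st$u), 1e-300)
    M0 <- length(lambdas) * o
    logdet <- 2 * sum(log(diag(R)))
    (st$n - M0) * log(rss_pen) + logdet -
      sum((c - o) * log(st$N * lambdas))
  } else {
    rss <- max(st$q - 2 * sum(theta * st$u) +
                 drop(crossprod(theta, st$S %*% theta)), 1e-300)
    edf <- sum(diag(chol2inv(R) %*% st$S))
    st$n * rss / (st$n - min(edf, st$n - 1e-8))^2
  }
}

# per-block effective degrees of freedom tr[(S + S_lam)^-1 S] restricted to
# block p
block_edf <- function(st, lambdas, c, o = 2L) {
  M <- st$S + st$N * block_penalty(lambdas, c, o)
  H <- solve(M, st$S)
  vapply(seq_along(lambdas), function(p) {
    ix <- ((p - 1L) * c + 1L):(p * c)
    sum(diag(H[ix, ix, drop = FALSE]))
  }, numeric(1))
}

#' Select smoothing parameters
#'
#' Chooses per-block smoothing parameters by minimizing a REML criterion of
#' the equivalent variance-components model after pre-whitening by
#' `V_i^{-1/2}` (default), or GCV, by coordinate descent: a log10 grid search
#' over `10^-6..10^8` per block followed by golden-section refinement,
#' repeated for two sweeps.
#'
#' @param blocks Design blocks from [assemble_design()].
#' @param Gamma,sigma2 Variance components defining `V_i`.
#' @param c Basis dimension per block; `o` penalty order.
#' @param selector `"reml"` or `"gcv"`.
#' @param n_blocks Number of coefficient-function blocks (P + 1).
#' @return Numeric vector of selected lambdas.
#' @export
select_smoothing <- function(blocks, Gamma = NULL, sigma2 = 1, c, o = 2L,
                             selector = c("reml", "gcv"), n_blocks) {
  selector <- match.arg(selector)
  st <- pgls_stats(blocks, Gamma, sigma2)
  select_smoothing_stats(st, c, o, selector, n_blocks)
}

select_smoothing_stats <- function(st, c, o, selector, n_blocks) {
  crit <- function(lam) selection_criterion(st, lam, c, o, selector)
  lam <- rep(1, n_blocks)
  grid <- 10^seq(-6, 8, by = 1)
  for (sweep in 1:2) {
    for (p in seq_len(n_blocks)) {
      vals <- vapply(grid, function(g) {
        l <- lam; l[p] <- g; crit(l)
      }, numeric(1))
      if (all(!is.finite(vals)))
        stop("smoothing selection failed: criterion non-finite on grid")
      l0 <- log10(grid[which.min(vals)])
      # golden-section refinement on [l0 - 1, l0 + 1] (log10 scale)
      gr <- (sqrt(5) - 1) / 2
      a <- l0 - 1; b <- l0 + 1
      x1 <- b - gr * (b - a); x2 <- a + gr * (b - a)
      f1 <- crit(replace(lam, p, 10^x1)); f2 <- crit(replace(lam, p, 10^x2))
      for (it in 1:12) {
        if (f1 <= f2) {
          b <- x2; x2 <- x1; f2 <- f1
          x1 <- b - gr * (b - a); f1 <- crit(replace(lam, p, 10^x1))
        } else {
          a <- x1; x1 <- x2; f1 <- f2
          x2 <- a + gr * (b - a); f2 <- crit(replace(lam, p, 10^x2))
        }
      }
      lam[p] <- 10^((a + b) / 2)
      if (crit(lam) > min(vals)) lam[p] <- grid[which.min(vals)]
    }
  }
  lam
}

# ---- full model fit ------------------------------------------------------

#' Fit a dynamic functional concurrent regression model
#'
#' Estimates time-varying coefficient functions for an intercept,
#' time-invariant covariates and (error-contaminated) time-varying covariates,
#' together with the covariance of a spline-based functional random intercept.
#' Time-varying covariates are first denoised by sparse FPCA and replaced by
#' their BLUP reconstruction at the outcome visit times.
#'
#' Estimation uses the 4-step procedure: (1) penalized GLS with `V_i = I`;
#' (2) covariance smoothing of the residuals giving `(Gamma, sigma2)`;
#' (3) penalized GLS with `V_i = B_i Gamma B_i' + sigma2 I`;
#' (4) final covariance re-estimation from the updated residuals. Smoothing
#' parameters are reselected at each GLS step.
#'
#' @param data Long-format data frame, one row per subject-visit.
#' @param id,time,outcome Column names.
#' @param invariant Character vector of time-invariant covariate columns.
#' @param varying Character vector of time-varying covariate columns.
#' @param basis An [fcr_basis()]; built from the pooled outcome times with
#'   `n_interior` interior knots when `NULL`.
#' @param n_interior Interior-knot count for the default basis.
#' @param n_interior_cov Optional interior-knot count for a separate (usually
#'   smaller) basis used for the functional random intercept and its
#'   covariance. `NULL` (default) shares the coefficient-function basis. A
#'   reduced basis lowers the parameter count of the covariance estimate
#'   (`c(c+1)/2`), which stabilizes the plug-in GLS weights in moderate
#'   samples.
#' @param o Difference-penalty order (2 throughout).
#' @param selector Smoothing-parameter criterion, `"reml"` (default) or
#'   `"gcv"`.
#' @param cycles Number of full variance-update cycles (steps 3-4); 1 by
#'   default.
#' @param covariate_models Optional pre-fitted `fpca_model`s for the varying
#'   covariates (named list); fitted internally when absent.
#' @return An object of class `fcr_fit`.
#' @examples
#' sc <- sim_scenario(N = 40, m_range = c(8, 12))
#' d <- generate_dataset(sc, seed = 1)
#' fit <- fit_fcr(d$train, invariant = "sex", varying = "waz",
#'                n_interior = 4)
#' head(coefficient_function(fit, 0, seq(0, 1, length.out = 5)))
#' @export
fit_fcr <- function(data, id = "id", time = "time", outcome = "y",
                    invariant = character(), varying = character(),
                    basis = NULL, n_interior = 6L, n_interior_cov = NULL,
                    o = 2L, selector = c("reml", "gcv"), cycles = 1L,
                    covariate_models = NULL) {
  selector <- match.arg(selector)
  if (nrow(data) == 0L) stop("empty data")
  if (is.null(basis))
    basis <- fcr_basis(data[[time]], n_interior = n_interior)
  c <- basis$c
  rand_basis <- if (is.null(n_interior_cov)) basis else
    fcr_basis(c(basis$boundary, data[[time]]),
              n_interior = as.integer(n_interior_cov))

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
  if (!identical(rand_basis, basis))
    for (i in seq_along(blocks))
      blocks[[i]]$Bc <- eval_basis(rand_basis, blocks[[i]]$t)
  if (!any(vapply(blocks, function(b) b$m >= 2L, logical(1))))
    stop("need at least one subject with two or more visits")
  nb <- 1L + length(invariant) + length(varying)

  # step 1: working independence
  st0 <- pgls_stats(blocks, Gamma = NULL, sigma2 = 1)
  lam <- select_smoothing_stats(st0, c, o, selector, nb)
  fit0 <- pgls_from_stats(st0, lam, c, o)
  theta <- fit0$theta

  resid_df <- function(th) {
    do.call(rbind, lapply(blocks, function(bl)
      data.frame(id = bl$id, time = bl$t,
                 value = bl$y - drop(bl$X %*% th))))
  }

  # step 2: variance components from working-independence residuals
  rmod <- estimate_covariance(resid_df(theta), rep(0, rand_basis$c),
                              rand_basis, o = o)
  Gamma <- rmod$gamma; sigma2 <- rmod$error_var
  fit1 <- fit0

  for (cy in seq_len(cycles)) {
    # step 3: penalized GLS under the estimated V_i
    st1 <- pgls_stats(blocks, Gamma = Gamma, sigma2 = sigma2)
    lam <- select_smoothing_stats(st1, c, o, selector, nb)
    fit1 <- pgls_from_stats(st1, lam, c, o)
    theta <- fit1$theta
    # step 4: final variance components from updated residuals
    rmod <- estimate_covariance(resid_df(theta), rep(0, rand_basis$c),
                                rand_basis, o = o)
    Gamma <- rmod$gamma; sigma2 <- rmod$error_var
  }

  terms <- c("(Intercept)", invariant, varying)
  structure(
    list(model = if (nb == 1L) "fri" else "fcr", basis = basis,
         rand_basis = rand_basis,
         theta = fit1$theta, lambdas = fit1$lambdas,
         cov_theta = fit1$cov_theta, cov_bayes = fit1$cov_bayes,
         Gamma = Gamma, sigma2 = sigma2,
         random_model = rmod, covariate_models = cov_models,
         terms = terms, invariant = invariant, varying = varying,
         selector = selector, o = o, N = length(blocks),
         t_max = max(data[[time]]),
         columns = list(id = id, time = time, outcome = outcome)),
    class = "fcr_fit"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Extract an estimated coefficient function
#'
#' Evaluates `f_p(t) = B(t)' theta_p` with pointwise standard errors and 95%
#' confidence limits (`estimate +/- 1.96 se`). By default the standard errors
#' propagate the model-based (Bayesian) covariance `(A + P)^-1 / N`, which
#' accounts for penalty-induced bias and gives near-nominal pointwise
#' coverage for penalized splines; `interval = "sandwich"` uses the
#' frequentist sandwich covariance instead (narrower under heavy smoothing).
#'
#' @param fit An `fcr_fit` (or `amm_fit`).
#' @param term Coefficient-function index (0 = intercept, 1..P) or name.
#' @param t Evaluation times.
#' @param interval Covariance used for the bands: `"bayes"` (default) or
#'   `"sandwich"`.
#' @return Data frame with columns `t`, `estimate`, `se`, `lo95`, `hi95`.
#' @export
coefficient_function <- function(fit, term, t,
                                 interval = c("bayes", "sandwich")) {
  interval <- match.arg(interval)
  c <- fit$basis$c
  if (is.character(term)) {
    p <- match(term, fit$terms)
    if (is.na(p)) stop("unknown coefficient function: ", term)
  } else {
    p <- as.integer(term) + 1L
    if (p < 1L || p > length(fit$terms)) stop("coefficient index out of range")
  }
  ix <- ((p - 1L) * c + 1L):(p * c)
  B <- eval_basis(fit$basis, t)
  est <- drop(B %*% fit$theta[ix])
  Vfull <- if (interval == "bayes" && !is.null(fit$cov_bayes))
    fit$cov_bayes else fit$cov_theta
  Vb <- Vfull[ix, ix, drop = FALSE]
  se <- sqrt(pmax(rowSums((B %*% Vb) * B), 0))
  data.frame(t = t, estimate = est, se = se,
             lo95 = est - 1.96 * se, hi95 = est + 1.96 * se)
}

#' @export
print.fcr_fit <- function(x, ...) {
  cat("Functional concurrent regression fit (", toupper(x$model), ")\n",
      sep = "")
  cat("  subjects:", x$N, " basis dim:", x$basis$c, "\n")
  cat("  coefficient functions:", paste(x$terms, collapse = ", "), "\n")
  cat("  sigma2 =", format(x$sigma2, digits = 4),
      " tr(Gamma kernel) =",
      format(sum(gamma_eigen(x$Gamma, x$rand_basis %||% x$basis,
                             clamp = TRUE)$values), digits = 4), "\n")
  invisible(x)
}
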