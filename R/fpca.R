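## Sparse functional principal component analysis:
## penalized-spline mean, tensor-product P-spline covariance smoothing of
## residual cross-products, PSD projection, eigendecomposition of the
## covariance operator, and conditional-expectation (BLUP) curve
## reconstruction for sparsely observed functional variables.

# split long data into per-subject lists, sorted by time
split_functions <- function(data, id = "id", time = "time", value = "value") {
  stopifnot(all(c(id, time, value) %in% names(data)))
  ord <- order(data[[id]], data[[time]])
  data <- data[ord, , drop = FALSE]
  idx <- split(seq_len(nrow(data)), data[[id]])
  lapply(idx, function(i)
    list(times = as.numeric(data[[time]][i]),
         values = as.numeric(data[[value]][i])))
}

# 1-D penalized-spline fit with GCV-selected smoothing on a log grid.
pspline_fit <- function(x, y, basis, o = 2L,
                        loglambda = seq(-6, 8, length.out = 29)) {
  B <- eval_basis(basis, x)
  n <- length(y)
  S <- crossprod(B)
  u <- crossprod(B, y)
  yy <- sum(y^2)
  P <- difference_penalty(basis$c, o)$matrix
  best <- NULL
  for (ll in loglambda) {
    lam <- 10^ll
    M <- S + lam * P
    cf <- tryCatch(solve(M, u), error = function(e) NULL)
    if (is.null(cf)) next
    edf <- sum(diag(solve(M, S)))
    rss <- max(yy - 2 * sum(cf * u) + drop(crossprod(cf, S %*% cf)), 0)
    gcv <- n * rss / (n - min(edf, n - 1e-8))^2
    if (is.null(best) || gcv < best$gcv)
      best <- list(coeffs = drop(cf), lambda = lam, gcv = gcv, edf = edf)
  }
  if (is.null(best)) stop("rank-deficient normal equations in penalized fit")
  best
}

#' Estimate the mean function of a sparsely observed functional variable
#'
#' Pools all observations and fits a penalized B-spline regression of value
#' on time with a second-order difference penalty; the smoothing parameter is
#' chosen by generalized cross-validation.
#'
#' @param data Long-format data frame with columns `id`, `time`, `value`
#'   (names configurable).
#' @param basis An [fcr_basis()].
#' @param id,time,value Column names.
#' @return Numeric vector of basis coefficients for the mean, with the chosen
#'   smoothing parameter attached as attribute `"lambda"`.
#' @export
estimate_mean <- function(data, basis, id = "id", time = "time",
                          value = "value") {
  if (nrow(data) <= basis$c)
    stop("need more pooled observations than basis functions")
  fit <- pspline_fit(data[[time]], data[[value]], basis)
  structure(fit$coeffs, lambda = fit$lambda)
}

# duplication map: vech index table for symmetric c x c matrices
vech_pairs <- function(c) {
  lo <- which(lower.tri(diag(c), diag = TRUE), arr.ind = TRUE)
  list(row = lo[, 1], col = lo[, 2])
}

vech_to_mat <- function(g, c) {
  M <- matrix(0, c, c)
  M[lower.tri(M, diag = TRUE)] <- g
  M <- M + t(M)
  diag(M) <- diag(M) / 2
  M
}

# penalty on the vech parameterization of Gamma induced by
# lambda * (P (x) I + I (x) P) on vec(Gamma)
vech_penalty <- function(c, o = 2L) {
  P1 <- difference_penalty(c, o)$matrix
  Pfull <- kronecker(P1, diag(c)) + kronecker(diag(c), P1)
  vp <- vech_pairs(c)
  ns <- length(vp$row)
  Dup <- matrix(0, c * c, ns)
  for (s in seq_len(ns)) {
    i <- vp$row[s]; j <- vp$col[s]
    Dup[i + (j - 1L) * c, s] <- Dup[i + (j - 1L) * c, s] + 1
    if (i != j) Dup[j + (i - 1L) * c, s] <- Dup[j + (i - 1L) * c, s] + 1
  }
  list(P = crossprod(Dup, Pfull %*% Dup), Dup = Dup, pairs = vp)
}

#' Estimate a smooth covariance surface and error variance
#'
#' Given demeaned residuals of a sparsely observed functional variable, fits
#' the coefficient matrix `Gamma` of the covariance expansion
#' `C(s,t) = sum_kl Gamma[k,l] B_k(s) B_l(t)` by penalized regression of the
#' off-diagonal residual cross-products on the symmetrized tensor-product
#' basis, projects `Gamma` to positive semidefiniteness (in the L2 geometry of
#' the basis), and estimates the white-noise error variance from the gap
#' between the smoothed raw diagonal and the fitted surface diagonal over the
#' central 80% of the domain.
#'
#' @param data Long-format data frame (`id`, `time`, `value`).
#' @param mean_coeffs Basis coefficients of the mean function (values are
#'   demeaned internally); pass zeros to treat `value` as already centred.
#' @param basis An [fcr_basis()].
#' @param o Difference-penalty order.
#' @param id,time,value Column names.
#' @param band Bandwidth (fraction of the domain range) for the local
#'   variogram regression that estimates the error variance (default 0.1).
#' @param lambda Optional fixed smoothing parameter for the covariance
#'   surface; when `NULL` (default) it is selected by GCV.
#' @return An object of class `fpca_model` with fields `basis`, `mean_coeffs`,
#'   `gamma`, `error_var`, `evalues`, `efuncs` (L2-orthonormal eigenfunction
#'   coefficients) and `lambda_cov` (chosen smoothing parameter).
#' @export
estimate_covariance <- function(data, mean_coeffs, basis, o = 2L,
                                id = "id", time = "time", value = "value",
                                band = 0.1, lambda = NULL) {
  subs <- split_functions(data, id, time, value)
  c <- basis$c
  vp <- vech_penalty(c, o)
  ns <- length(vp$pairs$row)

  rows_list <- vector("list", length(subs))
  resp_list <- vector("list", length(subs))
  gap_list <- vector("list", length(subs))
  hdf_list <- vector("list", length(subs))
  for (si in seq_along(subs)) {
    s <- subs[[si]]
    B <- eval_basis(basis, s$times)
    r <- s$values - drop(B %*% mean_coeffs)
    m <- length(r)
    if (m < 2L) next
    pr <- which(upper.tri(matrix(0, m, m)), arr.ind = TRUE)
    J <- pr[, 1]; K <- pr[, 2]
    A <- B[J, , drop = FALSE]; Bm <- B[K, , drop = FALSE]
    G <- matrix(0, length(J), ns)
    for (sx in seq_len(ns)) {
      a <- vp$pairs$row[sx]; b <- vp$pairs$col[sx]
      G[, sx] <- if (a == b) A[, a] * Bm[, a] else
        A[, a] * Bm[, b] + A[, b] * Bm[, a]
    }
    rows_list[[si]] <- G
    resp_list[[si]] <- r[J] * r[K]
    gap_list[[si]] <- s$times[K] - s$times[J]
    hdf_list[[si]] <- 0.5 * (r[K] - r[J])^2
  }
  Gd <- do.call(rbind, rows_list)
  w <- unlist(resp_list)
  if (is.null(Gd) || nrow(Gd) == 0L)
    stop("cannot identify covariance: no within-subject off-diagonal pairs")

  S <- crossprod(Gd)
  u <- crossprod(Gd, w)
  yy <- sum(w^2)
  n <- length(w)
  best <- NULL
  lam_grid <- if (is.null(lambda)) 10^seq(-6, 8, length.out = 15) else lambda
  for (lam in lam_grid) {
    M <- S + lam * vp$P
    cf <- tryCatch(solve(M, u), error = function(e) NULL)
    if (is.null(cf)) next
    edf <- sum(diag(solve(M, S)))
    rss <- max(yy - 2 * sum(cf * u) + drop(crossprod(cf, S %*% cf)), 0)
    gcv <- n * rss / (n - min(edf, n - 1e-8))^2
    if (is.null(best) || gcv < best$gcv)
      best <- list(g = drop(cf), lambda = lam, gcv = gcv)
  }
  if (is.null(best)) stop("covariance smoothing failed: singular system")
  Gam <- vech_to_mat(best$g, c)
  Gam <- (Gam + t(Gam)) / 2

  # PSD projection + eigendecomposition in the L2 geometry
  ed <- gamma_eigen(Gam, basis, clamp = TRUE)
  Gam <- ed$gamma

  # error variance by local variogram regression: for within-subject pairs
  # with small time gaps d, E[ (r_j - r_k)^2 / 2 ] = sigma2 + smooth O(d)
  # structure; the intercept of a quadratic-in-d fit over gaps below `band`
  # of the domain range estimates the nugget sigma2. This avoids the bias of
  # comparing two independently smoothed surfaces on the diagonal.
  gaps <- unlist(gap_list)
  hdf <- unlist(hdf_list)
  keep <- gaps <= band * diff(basis$boundary)
  if (sum(keep) < 30L) {
    ord <- order(gaps)
    keep <- ord[seq_len(min(length(gaps), max(30L, length(gaps) %/% 10L)))]
  }
  dk <- gaps[keep]; vk <- hdf[keep]
  sig2 <- if (all(vk == 0)) 0 else {
    # polynomial degree adapted to the number of distinct gap values
    deg <- min(2L, length(unique(dk)) - 1L)
    cf <- if (deg < 1L) mean(vk) else {
      Xv <- outer(dk, 0:deg, "^")
      tryCatch(drop(solve(crossprod(Xv), crossprod(Xv, vk)))[1],
               error = function(e) mean(vk))
    }
    max(cf, 0)
  }

  structure(
    list(basis = basis, mean_coeffs = as.numeric(mean_coeffs), gamma = Gam,
         error_var = sig2, evalues = ed$values, efuncs = ed$coeffs,
         lambda_cov = best$lambda),
    class = "fpca_model"
  )
}

# eigendecomposition of the integral operator with kernel B(s)' Gamma B(t),
# via the basis Gram matrix; optionally clamps negative eigenvalues (PSD
# projection). Returns eigenfunction coefficients orthonormal in L2.
gamma_eigen <- function(gamma, basis, clamp = FALSE) {
  G <- basis_gram(basis)
  U <- chol(G)
  M <- U %*% gamma %*% t(U)
  M <- (M + t(M)) / 2
  e <- eigen(M, symmetric = TRUE)
  vals <- e$values
  if (clamp) vals <- pmax(vals, 0)
  Mplus <- e$vectors %*% (vals * t(e$vectors))
  gplus <- backsolve(U, t(backsolve(U, t(Mplus))))
  gplus <- (gplus + t(gplus)) / 2
  coeffs <- backsolve(U, e$vectors)
  list(values = vals, coeffs = coeffs, gamma = gplus)
}

#' Eigendecomposition of a fitted covariance model
#'
#' Returns the leading eigenvalues and L2-orthonormal eigenfunctions of the
#' integral operator with kernel `C(s,t) = B(s)' Gamma B(t)`. The truncation
#' keeps the smallest K reaching a 0.9999 cumulative eigenvalue share (or all
#' `c` components).
#'
#' @param model An `fpca_model`.
#' @param share Cumulative-share truncation threshold.
#' @return List with `values` (nonincreasing) and `coeffs` (c x K matrix of
#'   eigenfunction basis coefficients).
#' @export
eigendecompose <- function(model, share = 0.9999) {
  ed <- gamma_eigen(model$gamma, model$basis, clamp = TRUE)
  vals <- ed$values
  tot <- sum(vals)
  K <- if (tot <= 0) 1L else
    min(which(cumsum(vals) / tot >= share), length(vals))
  list(values = vals[seq_len(K)], coeffs = ed$coeffs[, seq_len(K), drop = FALSE])
}

#' Evaluate a fitted covariance surface
#'
#' @param model An `fpca_model`.
#' @param s,t Numeric vectors of times.
#' @return `length(s) x length(t)` matrix of `C(s,t)` values.
#' @export
cov_surface <- function(model, s, t = s) {
  Bs <- eval_basis(model$basis, s)
  Bt <- eval_basis(model$basis, t)
  Bs %*% model$gamma %*% t(Bt)
}

#' Evaluate the fitted mean function
#'
#' @param model An `fpca_model`.
#' @param t Numeric vector of times.
#' @export
mean_function <- function(model, t) {
  drop(eval_basis(model$basis, t) %*% model$mean_coeffs)
}

#' BLUP reconstruction of a sparsely observed curve
#'
#' Conditional expectation (and variance) of the latent smooth curve given
#' noisy observations, under the fitted Gaussian-process model:
#' `Ztilde(t) = mu(t) + C(t, t_obs) [C(t_obs, t_obs) + sigma2 I]^{-1} (z - mu(t_obs))`.
#'
#' @param model An `fpca_model`.
#' @param times,values Observed times and values (may be empty: returns the
#'   prior mean and variance).
#' @param t_new Times at which to reconstruct the curve.
#' @return List with `mean` and `var` (pointwise) at `t_new`.
#' @export
blup_curve <- function(model, times, values, t_new) {
  Bn <- eval_basis(model$basis, t_new)
  mu_new <- drop(Bn %*% model$mean_coeffs)
  prior_var <- rowSums((Bn %*% model$gamma) * Bn)
  if (length(times) == 0L)
    return(list(mean = mu_new, var = prior_var))
  Bo <- eval_basis(model$basis, times)
  mu_obs <- drop(Bo %*% model$mean_coeffs)
  Koo <- Bo %*% model$gamma %*% t(Bo) + model$error_var * diag(length(times))
  R <- tryCatch(chol(Koo), error = function(e) NULL)
  if (is.null(R) || min(diag(R)) <= 1e-6 * max(diag(R)))
    stop("singular observation covariance (duplicated times with zero error ",
         "variance?); add jitter or a positive error variance")
  Kno <- Bn %*% model$gamma %*% t(Bo)
  alpha <- backsolve(R, backsolve(R, values - mu_obs, transpose = TRUE))
  W <- backsolve(R, t(Kno), transpose = TRUE)  # R^-T Kno'
  list(mean = mu_new + drop(Kno %*% alpha),
       var = pmax(prior_var - colSums(W^2), 0))
}

#' Sparse FPCA in one call
#'
#' Convenience wrapper: estimates the mean, the covariance surface and error
#' variance, and the eigenstructure of a sparsely observed functional
#' variable.
#'
#' @inheritParams estimate_mean
#' @param ... Passed to [estimate_covariance()].
#' @return An `fpca_model` (see [estimate_covariance()]).
#' @export
fpca_sparse <- function(data, basis, id = "id", time = "time",
                        value = "value", ...) {
  mu <- estimate_mean(data, basis, id, time, value)
  estimate_covariance(data, mu, basis, id = id, time = time, value = value,
                      ...)
}

#' @export
print.fpca_model <- function(x, ...) {
  cat("Sparse FPCA model: c =", x$basis$c, "basis functions\n")
  cat("  error variance:", format(x$error_var, digits = 4), "\n")
  ev <- x$evalues[x$evalues > 1e-12 * max(x$evalues, 1e-300)]
  cat("  leading eigenvalues:",
      paste(format(utils::head(ev, 5), digits = 3), collapse = ", "), "\n")
  invisible(x)
}
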