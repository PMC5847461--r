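make_long <- function(ids, times, values) {
  data.frame(id = ids, time = times, value = values)
}

test_that("mean estimation handles degenerate and smooth cases", {
  set.seed(2)
  basis <- fcr_basis(seq(0, 1, length.out = 100), n_interior = 6)
  n_sub <- 50; m <- 10
  ids <- rep(sprintf("s%02d", 1:n_sub), each = m)
  tt <- runif(n_sub * m)

  # all-zero data give a zero mean function
  mu0 <- estimate_mean(make_long(ids, tt, rep(0, length(tt))), basis)
  expect_lt(max(abs(mu0)), 1e-10)

  # constants are in the penalty null space: exact fit at any smoothing
  muc <- estimate_mean(make_long(ids, tt, rep(3.5, length(tt))), basis)
  g <- seq(0, 1, length.out = 101)
  expect_equal(drop(eval_basis(basis, g) %*% muc), rep(3.5, 101),
               tolerance = 1e-8)

  # smooth truth with small noise recovered accurately
  n_sub <- 200; m <- 20
  ids <- rep(sprintf("s%03d", 1:n_sub), each = m)
  tt <- runif(n_sub * m)
  y <- sin(2 * pi * tt) + rnorm(length(tt), 0, 0.01)
  mus <- estimate_mean(make_long(ids, tt, y), basis)
  est <- drop(eval_basis(basis, g) %*% mus)
  expect_lt(ise(sin(2 * pi * g), est, g), 1e-2)
})

test_that("zero residuals give a zero covariance model", {
  basis <- fcr_basis(seq(0, 1, length.out = 50), n_interior = 4)
  ids <- rep(c("a", "b", "c"), each = 8)
  tt <- rep(seq(0.05, 0.95, length.out = 8), 3)
  m0 <- estimate_covariance(make_long(ids, tt, rep(0, 24)), rep(0, basis$c),
                            basis)
  expect_lt(max(abs(m0$gamma)), 1e-10)
  expect_equal(m0$error_var, 0)
})

test_that("covariance smoother recovers a known coefficient matrix on
           noiseless in-span data", {
  set.seed(7)
  basis <- fcr_basis(seq(0, 1, length.out = 100), n_interior = 2)  # c = 6
  c <- basis$c
  A <- matrix(rnorm(c * c, sd = 0.4), c)
  Gam0 <- crossprod(A) / c
  # balanced score design: cycling u = sqrt(c) R' e_k makes the empirical
  # second moment of the coefficients exactly Gam0, so only smoother algebra
  # (not subject sampling) is tested
  R <- chol(Gam0)
  tt <- seq(0.02, 0.98, length.out = 21)
  rows <- lapply(seq_len(5 * c), function(i) {
    k <- 1L + (i - 1L) %% c
    u <- sqrt(c) * drop(t(R) %*% diag(c)[, k])
    data.frame(id = i, time = tt,
               value = drop(eval_basis(basis, tt) %*% u))
  })
  dat <- do.call(rbind, rows)
  # vanishing smoothing: the regression recovers the second-moment matrix
  fit <- estimate_covariance(dat, rep(0, c), basis, lambda = 1e-8)
  relerr <- norm(fit$gamma - Gam0, "F") / norm(Gam0, "F")
  expect_lt(relerr, 0.05)
  # noiseless curves: nugget estimate small relative to the curve variance
  # (two distinct small gaps only, so the variogram fit is linear here)
  expect_lt(fit$error_var, 0.05 * max(diag(Gam0)))
})

two_ef_sim <- function(seed, n_sub = 200, m = 20, lam = c(0.6, 0.2),
                       sig = 0.1) {
  set.seed(seed)
  rows <- lapply(seq_len(n_sub), function(i) {
    tt <- sort(runif(m))
    xi <- rnorm(2, 0, sqrt(lam))
    val <- xi[1] * 1 + xi[2] * sqrt(2) * cos(2 * pi * tt) + rnorm(m, 0, sig)
    data.frame(id = i, time = tt, value = val)
  })
  do.call(rbind, rows)
}

test_that("eigenvalues and error variance recovered in the two-eigenfunction
           model", {
  basis <- fcr_basis(seq(0, 1, length.out = 100), n_interior = 6)
  lam_err <- c(); sig_err <- c()
  for (seed in 1:7) {
    dat <- two_ef_sim(seed)
    fit <- estimate_covariance(dat, rep(0, basis$c), basis)
    ev <- fit$evalues[1:2]
    lam_err <- rbind(lam_err, abs(ev - c(0.6, 0.2)) / c(0.6, 0.2))
    sig_err <- c(sig_err, abs(fit$error_var - 0.01) / 0.01)
  }
  expect_lt(median(lam_err[, 1]), 0.15)
  expect_lt(median(lam_err[, 2]), 0.15)
  expect_lt(median(sig_err), 0.20)
})

test_that("eigenvalue estimation error shrinks with more subjects", {
  basis <- fcr_basis(seq(0, 1, length.out = 100), n_interior = 6)
  err_at <- function(n) {
    e <- sapply(1:3, function(s) {
      fit <- estimate_covariance(two_ef_sim(100 + s, n_sub = n),
                                 rep(0, basis$c), basis)
      sum(abs(fit$evalues[1:2] - c(0.6, 0.2)))
    })
    median(e)
  }
  expect_lt(err_at(1000), err_at(200))
})

test_that("eigendecomposition is orthonormal, trace-consistent, and detects
           rank", {
  set.seed(11)
  basis <- fcr_basis(seq(0, 1, length.out = 60), n_interior = 4)
  c <- basis$c
  # rank-1 coefficient matrix: exactly one nonzero eigenvalue
  v <- rnorm(c)
  m1 <- structure(list(basis = basis, mean_coeffs = rep(0, c),
                       gamma = tcrossprod(v), error_var = 0),
                  class = "fpca_model")
  ed1 <- eigendecompose(m1)
  expect_equal(length(ed1$values), 1L)
  full <- dynfcr:::gamma_eigen(tcrossprod(v), basis)$values
  expect_lt(max(abs(full[-1])) / full[1], 1e-10)

  # random PSD Gamma: sum of eigenvalues equals integral of the diagonal
  A <- matrix(rnorm(c * c), c)
  Gam <- crossprod(A) / c
  m2 <- structure(list(basis = basis, mean_coeffs = rep(0, c), gamma = Gam,
                       error_var = 0.1), class = "fpca_model")
  ed2 <- eigendecompose(m2, share = 1)
  g <- seq(0, 1, length.out = 4001)
  w <- dynfcr:::simpson_weights(4001, 1 / 4000)
  diag_c <- rowSums((eval_basis(basis, g) %*% Gam) * eval_basis(basis, g))
  expect_equal(sum(ed2$values), sum(w * diag_c), tolerance = 1e-6)

  # L2 orthonormality of eigenfunctions
  Phi <- eval_basis(basis, g) %*% ed2$coeffs
  Grm <- t(Phi) %*% (w * Phi)
  expect_lt(max(abs(Grm - diag(ncol(Phi)))), 1e-6)

  # PSD projection is idempotent and the surface is symmetric
  proj1 <- dynfcr:::gamma_eigen(Gam, basis, clamp = TRUE)$gamma
  proj2 <- dynfcr:::gamma_eigen(proj1, basis, clamp = TRUE)$gamma
  expect_equal(proj1, proj2, tolerance = 1e-9)
  s <- seq(0.1, 0.9, length.out = 9)
  C <- cov_surface(m2, s, s)
  expect_lt(max(abs(C - t(C))), 1e-10)
})

test_that("curve BLUP interpolates noiseless data and returns the prior when
           no data are observed", {
  set.seed(13)
  basis <- fcr_basis(seq(0, 1, length.out = 60), n_interior = 3)
  c <- basis$c
  A <- matrix(rnorm(c * c), c)
  Gam <- crossprod(A) / c
  mod <- structure(list(basis = basis, mean_coeffs = rnorm(c), gamma = Gam,
                        error_var = 0), class = "fpca_model")
  tt <- c(0.2, 0.5, 0.8)
  z <- rnorm(3)
  bl <- blup_curve(mod, tt, z, tt)
  expect_equal(bl$mean, z, tolerance = 1e-8)
  expect_lt(max(bl$var), 1e-8)

  pri <- blup_curve(mod, numeric(0), numeric(0), tt)
  expect_equal(pri$mean, mean_function(mod, tt))
  expect_equal(pri$var, diag(cov_surface(mod, tt, tt)), tolerance = 1e-12)
})

test_that("curve BLUP equals brute-force joint-Gaussian conditioning", {
  set.seed(17)
  basis <- fcr_basis(seq(0, 1, length.out = 60), n_interior = 4)
  c <- basis$c
  for (rep in 1:10) {
    A <- matrix(rnorm(c * c), c)
    Gam <- crossprod(A) / c
    sig2 <- runif(1, 0.01, 0.5)
    mod <- structure(list(basis = basis, mean_coeffs = rnorm(c), gamma = Gam,
                          error_var = sig2), class = "fpca_model")
    t_obs <- sort(runif(5)); t_new <- sort(runif(7))
    z <- rnorm(5)
    bl <- blup_curve(mod, t_obs, z, t_new)
    Bo <- eval_basis(basis, t_obs); Bn <- eval_basis(basis, t_new)
    orc <- joint_gauss_oracle(
      mu_obs = drop(Bo %*% mod$mean_coeffs),
      mu_new = drop(Bn %*% mod$mean_coeffs),
      S11 = Bo %*% Gam %*% t(Bo) + sig2 * diag(5),
      S12 = Bo %*% Gam %*% t(Bn),
      S22 = Bn %*% Gam %*% t(Bn), obs = z)
    expect_equal(bl$mean, orc$mean, tolerance = 1e-8)
    expect_equal(bl$var, orc$var, tolerance = 1e-8)
    # conditioning cannot inflate variance
    expect_true(all(bl$var <= diag(Bn %*% Gam %*% t(Bn)) + 1e-10))
  }
})

test_that("adding an observation never increases BLUP variance", {
  set.seed(19)
  basis <- fcr_basis(seq(0, 1, length.out = 60), n_interior = 4)
  c <- basis$c
  for (rep in 1:5) {
    A <- matrix(rnorm(c * c), c)
    mod <- structure(list(basis = basis, mean_coeffs = rep(0, c),
                          gamma = crossprod(A) / c, error_var = 0.2),
                     class = "fpca_model")
    t_obs <- sort(runif(6)); z <- rnorm(6)
    t_new <- seq(0.05, 0.95, length.out = 21)
    v_less <- blup_curve(mod, t_obs[-6], z[-6], t_new)$var
    v_more <- blup_curve(mod, t_obs, z, t_new)$var
    expect_true(all(v_more <= v_less + 1e-10))
  }
})

test_that("blup with zero error variance and duplicated times advises jitter", {
  basis <- fcr_basis(seq(0, 1, length.out = 30), n_interior = 2)
  c <- basis$c
  mod <- structure(list(basis = basis, mean_coeffs = rep(0, c),
                        gamma = diag(c), error_var = 0),
                   class = "fpca_model")
  expect_error(blup_curve(mod, c(0.5, 0.5), c(1, 1), 0.7), "jitter")
})
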