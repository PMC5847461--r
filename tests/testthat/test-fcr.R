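test_that("design assembly: intercept-only, indicator broadcast, and noiseless
           covariate interpolation", {
  set.seed(3)
  basis <- fcr_basis(seq(0, 1, length.out = 60), n_interior = 3)
  c <- basis$c
  tt <- sort(runif(6))
  d <- data.frame(id = "a", time = tt, y = rnorm(6), x = 1)

  bl0 <- assemble_design(d, basis)
  expect_equal(bl0[[1]]$X, bl0[[1]]$B)

  bl1 <- assemble_design(d, basis, invariant = "x")
  expect_equal(bl1[[1]]$X[, (c + 1):(2 * c)], bl1[[1]]$B)

  # noiseless covariate model observed at all outcome times: the BLUP block
  # reproduces the observed covariate exactly
  A <- matrix(rnorm(c * c), c)
  zmod <- structure(list(basis = basis, mean_coeffs = rep(0, c),
                         gamma = crossprod(A) / c, error_var = 0),
                    class = "fpca_model")
  u <- rnorm(c)
  d$z <- drop(eval_basis(basis, tt) %*% u)
  bl2 <- assemble_design(d, basis, varying = "z",
                         covariate_models = list(z = zmod))
  expect_equal(bl2[[1]]$Z[, 1], d$z, tolerance = 1e-8)

  expect_error(assemble_design(d, basis, varying = "z"), "covariate model")
  expect_error(assemble_design(d, basis, invariant = "nope"), "missing col")
})

test_that("penalized GLS reduces to OLS when Gamma = 0 and lambda = 0", {
  inst <- random_instance(101, N = 8, c = 5, P = 1)
  fit <- pgls_solve(inst$blocks, Gamma = NULL, sigma2 = 1,
                    lambdas = c(0, 0), c = inst$c)
  Xs <- do.call(rbind, lapply(inst$blocks, function(b) b$X))
  ys <- unlist(lapply(inst$blocks, function(b) b$y))
  ols <- stats::lm.fit(Xs, ys)$coefficients
  expect_equal(fit$theta, unname(ols), tolerance = 1e-8)
})

test_that("penalized GLS matches the literal dense-assembly oracle", {
  set.seed(500)
  for (seed in 1:10) {
    inst <- random_instance(seed, N = sample(4:10, 1), c = sample(5:6, 1),
                            P = sample(0:2, 1))
    lam <- 10^runif(inst$P + 1, -3, 3)
    fit <- pgls_solve(inst$blocks, inst$Gamma, inst$sigma2, lam, inst$c)
    orc <- eq3_oracle(inst$blocks, inst$Gamma, inst$sigma2, lam, inst$c)
    expect_equal(fit$theta, orc$theta, tolerance = 1e-8)
    expect_equal(fit$cov_theta, orc$cov_theta, tolerance = 1e-8,
                 ignore_attr = TRUE)
  }
})

test_that("an infinite penalty with o = 2 forces an affine coefficient
           function", {
  inst <- random_instance(7, N = 10, c = 10, P = 1)
  fit <- pgls_solve(inst$blocks, inst$Gamma, inst$sigma2,
                    lambdas = c(1e10, 0.1), c = inst$c)
  th0 <- fit$theta[1:inst$c]
  expect_lt(max(abs(diff(th0, differences = 2))), 1e-6)
  # coefficients in the penalty null space give a function that is exactly
  # affine away from the repeated boundary knots (uniform Greville sites)
  ik <- inst$basis$interior_knots
  g <- seq(ik[2], ik[length(ik) - 1L], length.out = 50)
  f0 <- drop(eval_basis(inst$basis, g) %*% th0)
  sec <- f0[1] + (f0[50] - f0[1]) * (g - g[1]) / (g[50] - g[1])
  expect_lt(max(abs(f0 - sec)), 1e-5)
})

test_that("first-order condition of the penalized GLS normal equations", {
  inst <- random_instance(23, N = 8, c = 5, P = 1)
  lam <- c(2.5, 0.4)
  fit <- pgls_solve(inst$blocks, inst$Gamma, inst$sigma2, lam, inst$c)
  st <- fit$stats
  P <- dynfcr:::block_penalty(lam, inst$c, 2L)
  # sum_i X_i' V_i^-1 (y_i - X_i theta) = N * P theta
  lhs <- st$u - st$S %*% fit$theta
  rhs <- st$N * P %*% fit$theta
  expect_lt(max(abs(lhs - rhs)), 1e-6)
})

test_that("sandwich covariance collapses to the single-bread form without
           penalty", {
  inst <- random_instance(31, N = 10, c = 5, P = 0)
  fit <- pgls_solve(inst$blocks, inst$Gamma, inst$sigma2, lambdas = 0,
                    c = inst$c)
  A <- fit$stats$S / fit$stats$N
  expect_equal(fit$cov_theta, solve(A) / fit$stats$N, tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("REML criterion agrees with a dense log-determinant evaluation", {
  inst <- random_instance(57, N = 6, c = 5, P = 1)
  st <- dynfcr:::pgls_stats(inst$blocks, inst$Gamma, inst$sigma2)
  for (ll in c(-3, -1, 0, 1, 3)) {
    lam <- c(10^ll, 10^(ll / 2))
    mine <- dynfcr:::selection_criterion(st, lam, inst$c, 2L, "reml")
    orc <- reml_oracle(inst$blocks, inst$Gamma, inst$sigma2, lam, inst$c)
    expect_equal(mine, orc, tolerance = 1e-6)
  }
})

test_that("smoothing selection hits the boundary regimes", {
  set.seed(5)
  basis <- fcr_basis(seq(0, 1, length.out = 100), n_interior = 6)
  mk_blocks <- function(yfun, sd) {
    lapply(1:30, function(i) {
      tt <- sort(runif(12))
      B <- eval_basis(basis, tt)
      y <- yfun(tt) + rnorm(12, 0, sd)
      list(id = i, t = tt, y = y, B = B, Z = NULL, X = B, m = 12)
    })
  }
  # pure noise: maximal smoothing, effective df near the null-space dimension
  bl_noise <- mk_blocks(function(t) 0 * t, 1)
  lam_n <- select_smoothing(bl_noise, NULL, 1, c = basis$c, n_blocks = 1)
  st <- dynfcr:::pgls_stats(bl_noise, NULL, 1)
  expect_gt(lam_n, 1e4)
  expect_lt(dynfcr:::block_edf(st, lam_n, basis$c), 2.5)

  # noiseless spline-representable signal: minimal smoothing
  u <- rnorm(basis$c)
  bl_sig <- mk_blocks(function(t) drop(eval_basis(basis, t) %*% u), 0)
  lam_s <- select_smoothing(bl_sig, NULL, 1, c = basis$c, n_blocks = 1)
  expect_lt(lam_s, 1e-4)
})

test_that("effective degrees of freedom are nonincreasing in lambda", {
  inst <- random_instance(77, N = 10, c = 6, P = 0)
  st <- dynfcr:::pgls_stats(inst$blocks, inst$Gamma, inst$sigma2)
  edfs <- sapply(10^seq(-4, 6, by = 1), function(l)
    dynfcr:::block_edf(st, l, inst$c))
  expect_true(all(diff(edfs) <= 1e-8))
})

test_that("a deterministic mean with no subject deviations yields null
           variance components", {
  set.seed(9)
  rows <- lapply(1:40, function(i) {
    tt <- sort(runif(12))
    data.frame(id = i, time = tt, y = -1 + 0.5 * cos(2 * pi * tt))
  })
  d <- do.call(rbind, rows)
  fit <- fit_fcr(d, n_interior = 6)
  expect_lt(fit$sigma2, 1e-4)
  expect_lt(norm(fit$Gamma, "F"), 1e-3)
})

test_that("a second variance-update cycle barely changes the estimates", {
  sc <- sim_scenario(N = 200, m_range = c(15, 25))
  d <- generate_dataset(sc, seed = 21)
  basis <- fcr_basis(d$grid, n_interior = 6)
  f1 <- fit_fcr(d$train, invariant = "sex", varying = "waz", basis = basis,
                cycles = 1)
  f2 <- fit_fcr(d$train, invariant = "sex", varying = "waz", basis = basis,
                cycles = 2)
  g <- seq(0, 1, length.out = 200)
  # change in each coefficient function below 1% of the dominant coefficient
  # scale (f1 is identically zero in truth, so a self-relative metric would
  # be degenerate there)
  scale_max <- max(sapply(0:2, function(p)
    sqrt(ise(coefficient_function(f1, p, g)$estimate, 0 * g, g))))
  for (p in 0:2) {
    a <- coefficient_function(f1, p, g)$estimate
    b <- coefficient_function(f2, p, g)$estimate
    expect_lt(sqrt(ise(a, b, g)) / scale_max, 0.01)
  }
  expect_lt(abs(f2$sigma2 - f1$sigma2) / f1$sigma2, 0.01)
})

test_that("coefficient-function extraction propagates the covariance as
           stated", {
  basis <- fcr_basis(seq(0, 1, length.out = 30), n_interior = 2)
  c <- basis$c
  theta <- c(rnorm(c), rep(0, c))
  fit <- manual_fit(basis, theta, diag(c) * 0.1, 0.05, invariant = "x")
  g <- seq(0.1, 0.9, length.out = 11)
  # identity covariance block: se(t)^2 = ||B(t)||^2
  cf0 <- coefficient_function(fit, 0, g)
  B <- eval_basis(basis, g)
  expect_equal(cf0$se^2, rowSums(B^2), tolerance = 1e-12)
  # zero coefficient block: estimate identically zero, CI symmetric
  cf1 <- coefficient_function(fit, "x", g)
  expect_equal(cf1$estimate, rep(0, 11))
  expect_equal(cf1$hi95 - cf1$estimate, cf1$estimate - cf1$lo95)
  expect_equal(cf1$hi95, 1.96 * cf1$se)
  expect_error(coefficient_function(fit, 5, g), "out of range")
})
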