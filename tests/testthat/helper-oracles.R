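# Independent oracle implementations used across the suite. These deliberately
# avoid the package's computational path (Cholesky/backsolve accumulation) and
# assemble the defining formulas literally with dense solve()/determinant().

# Cox-de Boor recursion, coded directly from the recurrence
deboor_eval <- function(knots, ord, j, x) {
  if (ord == 1)
    return(as.numeric(knots[j] <= x & x < knots[j + 1]))
  d1 <- knots[j + ord - 1] - knots[j]
  d2 <- knots[j + ord] - knots[j + 1]
  a <- if (d1 > 0) (x - knots[j]) / d1 * deboor_eval(knots, ord - 1, j, x) else 0
  b <- if (d2 > 0) (knots[j + ord] - x) / d2 *
    deboor_eval(knots, ord - 1, j + 1, x) else 0
  a + b
}

deboor_basis <- function(basis, x) {
  knots <- c(rep(basis$boundary[1], basis$order), basis$interior_knots,
             rep(basis$boundary[2], basis$order))
  sapply(seq_len(basis$c), function(j) deboor_eval(knots, basis$order, j, x))
}

# literal dense assembly of the penalized GLS estimator and its sandwich
# covariance
eq3_oracle <- function(blocks, Gamma, sigma2, lambdas, c, o = 2L) {
  N <- length(blocks)
  d <- ncol(blocks[[1]]$X)
  S <- matrix(0, d, d); u <- numeric(d)
  for (bl in blocks) {
    V <- if (is.null(Gamma)) sigma2 * diag(bl$m) else
      bl$B %*% Gamma %*% t(bl$B) + sigma2 * diag(bl$m)
    Vinv <- solve(V)
    S <- S + t(bl$X) %*% Vinv %*% bl$X
    u <- u + t(bl$X) %*% Vinv %*% bl$y
  }
  D <- diff(diag(c), differences = o)
  P <- matrix(0, d, d)
  for (p in seq_along(lambdas)) {
    ix <- ((p - 1) * c + 1):(p * c)
    P[ix, ix] <- lambdas[p] * crossprod(D)
  }
  Minv <- solve(S / N + P)
  theta <- Minv %*% (u / N)
  covt <- Minv %*% (S / N^2) %*% Minv
  list(theta = drop(theta), cov_theta = covt)
}

# brute-force Gaussian conditioning for curve reconstruction / prediction:
# joint covariance construction and block inversion
joint_gauss_oracle <- function(mu_obs, mu_new, S11, S12, S22, obs) {
  S11inv <- solve(S11)
  mean_c <- mu_new + t(S12) %*% S11inv %*% (obs - mu_obs)
  var_c <- S22 - t(S12) %*% S11inv %*% S12
  list(mean = drop(mean_c), var = diag(as.matrix(var_c)))
}

# random small concurrent-regression instance (blocks built directly)
random_instance <- function(seed, N = 6, c = 5, P = 1, m_range = c(3, 7)) {
  set.seed(seed)
  basis <- fcr_basis(seq(0, 1, length.out = 50), n_interior = c - 4L)
  A <- matrix(rnorm(c * c), c)
  Gamma <- 0.1 * crossprod(A) / c
  sigma2 <- 0.3
  blocks <- lapply(seq_len(N), function(i) {
    m <- sample(seq(m_range[1], m_range[2]), 1)
    t_i <- sort(runif(m))
    B <- eval_basis(basis, t_i)
    X <- B
    Z <- NULL
    if (P > 0) {
      Z <- matrix(rnorm(m * P), m, P)
      for (p in seq_len(P)) X <- cbind(X, Z[, p] * B)
    }
    y <- rnorm(m)
    list(id = paste0("s", i), t = t_i, y = y, B = B, Z = Z, X = X, m = m)
  })
  list(basis = basis, blocks = blocks, Gamma = Gamma, sigma2 = sigma2,
       c = c, P = P)
}

# dense REML criterion: whiten by eigendecomposition of V_i, stack, and use
# determinant() directly
reml_oracle <- function(blocks, Gamma, sigma2, lambdas, c, o = 2L) {
  Xs <- NULL; ys <- NULL
  N <- length(blocks)
  for (bl in blocks) {
    V <- if (is.null(Gamma)) sigma2 * diag(bl$m) else
      bl$B %*% Gamma %*% t(bl$B) + sigma2 * diag(bl$m)
    e <- eigen(V, symmetric = TRUE)
    W <- e$vectors %*% diag(1 / sqrt(e$values), bl$m) %*% t(e$vectors)
    Xs <- rbind(Xs, W %*% bl$X)
    ys <- c(ys, W %*% bl$y)
  }
  d <- ncol(Xs)
  D <- diff(diag(c), differences = o)
  P <- matrix(0, d, d)
  for (p in seq_along(lambdas)) {
    ix <- ((p - 1) * c + 1):(p * c)
    P[ix, ix] <- lambdas[p] * crossprod(D)
  }
  S <- t(Xs) %*% Xs
  M <- S + N * P
  theta <- solve(M, t(Xs) %*% ys)
  rss_pen <- sum((ys - Xs %*% theta)^2) + N * drop(t(theta) %*% P %*% theta)
  n <- length(ys)
  M0 <- length(lambdas) * o
  (n - M0) * log(rss_pen) +
    as.numeric(determinant(M, logarithm = TRUE)$modulus) -
    sum((c - o) * log(N * lambdas))
}

# dense AMM REML objective: blockdiagonal stacking and determinant()
amm_reml_oracle <- function(blocks, Psi, sigma2, lambdas, c, o = 2L) {
  N <- length(blocks)
  Vs <- lapply(blocks, function(bl) {
    Zi <- cbind(1, bl$t)
    Zi %*% Psi %*% t(Zi) + sigma2 * diag(bl$m)
  })
  n <- sum(vapply(blocks, function(b) b$m, numeric(1)))
  Vfull <- matrix(0, n, n)
  Xs <- NULL; ys <- NULL
  at <- 0
  for (i in seq_along(blocks)) {
    m <- blocks[[i]]$m
    Vfull[(at + 1):(at + m), (at + 1):(at + m)] <- Vs[[i]]
    Xs <- rbind(Xs, blocks[[i]]$X); ys <- c(ys, blocks[[i]]$y)
    at <- at + m
  }
  d <- ncol(Xs)
  D <- diff(diag(c), differences = o)
  P <- matrix(0, d, d)
  for (p in seq_along(lambdas)) {
    ix <- ((p - 1) * c + 1):(p * c)
    P[ix, ix] <- lambdas[p] * crossprod(D)
  }
  Vinv <- solve(Vfull)
  S <- t(Xs) %*% Vinv %*% Xs
  u <- t(Xs) %*% Vinv %*% ys
  theta <- solve(S + N * P, u)
  as.numeric(determinant(Vfull, logarithm = TRUE)$modulus) +
    as.numeric(determinant(S + N * P, logarithm = TRUE)$modulus) +
    drop(t(ys) %*% Vinv %*% ys) - drop(t(theta) %*% u)
}

# build a synthetic fcr_fit object with known parameters (no estimation)
manual_fit <- function(basis, theta, Gamma, sigma2, invariant = character(),
                       varying = character(), covariate_models = list(),
                       t_max = 1) {
  structure(
    list(model = "fcr", basis = basis, theta = theta,
         lambdas = rep(1, length(theta) / basis$c),
         cov_theta = diag(length(theta)), Gamma = Gamma, sigma2 = sigma2,
         covariate_models = covariate_models,
         terms = c("(Intercept)", invariant, varying),
         invariant = invariant, varying = varying, selector = "reml",
         o = 2L, N = 1L, t_max = t_max,
         columns = list(id = "id", time = "time", outcome = "y")),
    class = "fcr_fit")
}
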