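## Dynamic prediction: BLUP of a new subject's future trajectory from partial
## history, with pointwise prediction variance and +/- 2 sd limits.

# covariate values (invariant broadcast + varying BLUP) at arbitrary times,
# conditioning the varying-covariate reconstruction on the subject's
# covariate history up to the cutoff only
covariate_values_at <- function(fit, history, t_new, cutoff,
                                invariant_values = NULL,
                                future_covariates = NULL) {
  P <- length(fit$invariant) + length(fit$varying)
  Z <- matrix(0, length(t_new), P)
  p <- 0L
  for (v in fit$invariant) {
    p <- p + 1L
    val <- if (!is.null(invariant_values) && !is.null(invariant_values[[v]]))
      invariant_values[[v]]
    else if (nrow(history) > 0L && v %in% names(history))
      history[[v]][1]
    else stop("no value available for time-invariant covariate '", v, "'")
    Z[, p] <- as.numeric(val)
  }
  tcol <- fit$columns$time
  for (v in fit$varying) {
    p <- p + 1L
    if (!is.null(future_covariates) && !is.null(future_covariates[[v]])) {
      fc <- future_covariates[[v]]
      Z[, p] <- stats::approx(fc$time, fc$value, xout = t_new, rule = 2)$y
      next
    }
    if (nrow(history) > 0L && v %in% names(history)) {
      keep <- !is.na(history[[v]]) & history[[tcol]] <= cutoff
      bl <- blup_curve(fit$covariate_models[[v]],
                       history[[tcol]][keep], history[[v]][keep], t_new)
    } else {
      bl <- blup_curve(fit$covariate_models[[v]], numeric(0), numeric(0),
                       t_new)
    }
    Z[, p] <- bl$mean
  }
  Z
}

# fixed-effect part sum_p z_p(t) f_p(t) at given times
fixed_part <- function(fit, t, Z) {
  B <- eval_basis(fit$basis, t)
  c <- fit$basis$c
  out <- drop(B %*% fit$theta[seq_len(c)])
  P <- ncol(Z)
  if (P > 0)
    for (p in seq_len(P)) {
      ix <- (p * c + 1L):((p + 1L) * c)
      out <- out + Z[, p] * drop(B %*% fit$theta[ix])
    }
  out
}

#' Predict a new subject's trajectory dynamically
#'
#' Computes the BLUP of the functional random intercept from the subject's
#' observed outcome history up to `cutoff`,
#' `u_tilde = Gamma B*' (B* Gamma B*' + sigma2 I)^-1 (y - X theta)`,
#' and returns the predicted trajectory
#' `Y_tilde(t) = X(t) theta + B(t)' u_tilde` with pointwise prediction
#' variance
#' `B(t)'(Gamma - Gamma B*'(B* Gamma B*' + sigma2 I)^-1 B* Gamma)B(t) + sigma2`
#' and `+/- 2 sd` prediction limits. Time-varying covariate values at both
#' history and future times are replaced by their BLUP reconstruction
#' conditioned on the subject's covariate history up to the cutoff.
#'
#' @param fit A fitted model (`fcr_fit` or `amm_fit`).
#' @param history Long-format data frame with the subject's observed rows
#'   (may have zero rows: returns the population-level prediction).
#' @param t_grid Times at which to predict; must not exceed the training
#'   horizon `T_max`.
#' @param cutoff Latest history time used for conditioning (default: last
#'   observed time).
#' @param invariant_values Optional named list of time-invariant covariate
#'   values (needed when `history` is empty).
#' @param future_covariates Optional named list of data frames
#'   (`time`, `value`) supplying user-specified future covariate paths.
#' @return An object of class `fcr_prediction`: data frame with `t`, `y_hat`,
#'   `sd`, `lo95`, `hi95` plus attributes `u_tilde`, `cutoff`, `t_max`.
#' @export
predict_trajectory <- function(fit, history, t_grid, cutoff = NULL,
                               invariant_values = NULL,
                               future_covariates = NULL) {
  UseMethod("predict_trajectory")
}

check_horizon <- function(fit, t_grid) {
  tol <- 1e-8 * max(abs(fit$t_max), 1)
  if (any(t_grid > fit$t_max + tol))
    stop("extrapolation beyond T_max = ", fit$t_max,
         " (the latest training observation) is not supported")
}

prepare_history <- function(fit, history, cutoff) {
  tcol <- fit$columns$time; ycol <- fit$columns$outcome
  if (is.null(history) || nrow(history) == 0L) {
    history <- data.frame()
    cutoff <- cutoff %||% -Inf
    return(list(history = history, cutoff = cutoff,
                t_obs = numeric(0), y_obs = numeric(0)))
  }
  history <- history[order(history[[tcol]]), , drop = FALSE]
  cutoff <- cutoff %||% max(history[[tcol]])
  keep <- history[[tcol]] <= cutoff & !is.na(history[[ycol]])
  list(history = history, cutoff = cutoff,
       t_obs = history[[tcol]][keep], y_obs = history[[ycol]][keep])
}

#' @export
predict_trajectory.fcr_fit <- function(fit, history, t_grid, cutoff = NULL,
                                       invariant_values = NULL,
                                       future_covariates = NULL) {
  check_horizon(fit, t_grid)
  h <- prepare_history(fit, history, cutoff)
  Zg <- covariate_values_at(fit, h$history, t_grid, h$cutoff,
                            invariant_values, future_covariates)
  fixed_g <- fixed_part(fit, t_grid, Zg)
  rb <- fit$rand_basis %||% fit$basis
  Bg <- eval_basis(rb, t_grid)
  prior_var <- rowSums((Bg %*% fit$Gamma) * Bg)
  m <- length(h$t_obs)
  if (m == 0L) {
    u <- rep(0, rb$c)
    var_t <- prior_var + fit$sigma2
    yhat <- fixed_g
  } else {
    Zh <- covariate_values_at(fit, h$history, h$t_obs, h$cutoff,
                              invariant_values, future_covariates)
    fixed_h <- fixed_part(fit, h$t_obs, Zh)
    Bs <- eval_basis(rb, h$t_obs)
    K <- Bs %*% fit$Gamma %*% t(Bs) + fit$sigma2 * diag(m)
    R <- chol_jitter(K)
    resid <- h$y_obs - fixed_h
    GB <- fit$Gamma %*% t(Bs)                    # c x m
    alpha <- backsolve(R, backsolve(R, resid, transpose = TRUE))
    u <- drop(GB %*% alpha)
    W <- backsolve(R, t(Bg %*% GB), transpose = TRUE)  # R^-T (B* Gamma B(t)')
    var_t <- pmax(prior_var - colSums(W^2), 0) + fit$sigma2
    yhat <- fixed_g + drop(Bg %*% u)
  }
  sd_t <- sqrt(var_t)
  out <- data.frame(t = t_grid, y_hat = yhat, sd = sd_t,
                    lo95 = yhat - 2 * sd_t, hi95 = yhat + 2 * sd_t)
  structure(out, u_tilde = u, cutoff = h$cutoff, t_max = fit$t_max,
            class = c("fcr_prediction", "data.frame"))
}

#' Predict over a future window given history up to a cutoff
#'
#' Convenience wrapper around [predict_trajectory()] that validates the
#' (cutoff, window) configuration: the window must start after the cutoff.
#'
#' @param fit A fitted model.
#' @param history Subject history rows.
#' @param cutoff Conditioning time.
#' @param window Length-2 numeric `(a, b)` with `a > cutoff`.
#' @param t_grid Optional explicit grid inside the window (default 41 points).
#' @param ... Passed to [predict_trajectory()].
#' @export
predict_window <- function(fit, history, cutoff, window, t_grid = NULL, ...) {
  if (length(window) != 2L || window[1] >= window[2])
    stop("window must be an increasing (a, b) pair")
  if (window[1] <= cutoff)
    stop("invalid configuration: prediction window starts at ", window[1],
         ", not after the cutoff ", cutoff)
  t_grid <- t_grid %||% seq(window[1], window[2], length.out = 41)
  predict_trajectory(fit, history, t_grid, cutoff = cutoff, ...)
}

#' Dynamic-prediction schedule over cutoffs and windows
#'
#' Produces one prediction per valid (cutoff, window) pair, keeping the pairs
#' whose window lies strictly after the cutoff (and within the training
#' horizon).
#'
#' @param fit A fitted model.
#' @param history Subject history rows.
#' @param cutoffs Numeric vector of conditioning times.
#' @param windows List of length-2 numeric windows.
#' @param t_grid Optional list (parallel to `windows`) of evaluation grids.
#' @param ... Passed to [predict_trajectory()].
#' @return Data frame with one row per valid pair and a list-column
#'   `prediction` of `fcr_prediction` objects.
#' @export
dynamic_prediction_schedule <- function(fit, history, cutoffs, windows,
                                        t_grid = NULL, ...) {
  res <- list(); k <- 0L
  cut_v <- numeric(0); a_v <- numeric(0); b_v <- numeric(0)
  for (cu in cutoffs) {
    for (wi in seq_along(windows)) {
      w <- windows[[wi]]
      if (w[1] <= cu) next
      k <- k + 1L
      g <- if (!is.null(t_grid)) t_grid[[wi]] else NULL
      res[[k]] <- predict_window(fit, history, cu, w, t_grid = g, ...)
      cut_v[k] <- cu; a_v[k] <- w[1]; b_v[k] <- w[2]
    }
  }
  out <- data.frame(cutoff = cut_v, window_start = a_v, window_end = b_v)
  out$prediction <- res
  out
}

#' @export
plot.fcr_prediction <- function(x, history = NULL, time = "time",
                                outcome = "y", ...) {
  rng <- range(c(x$lo95, x$hi95,
                 if (!is.null(history)) history[[outcome]]))
  plot(x$t, x$y_hat, type = "l", ylim = rng, xlab = "time",
       ylab = "predicted outcome", ...)
  graphics::lines(x$t, x$lo95, lty = 2)
  graphics::lines(x$t, x$hi95, lty = 2)
  if (!is.null(history))
    graphics::points(history[[time]], history[[outcome]], pch = 16)
  graphics::abline(v = attr(x, "cutoff"), col = "grey", lty = 3)
  invisible(x)
}
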