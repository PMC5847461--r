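## Data ingestion and fit serialization.

#' Read long-format subject-visit data
#'
#' Reads a CSV, maps columns, sorts by subject and time, and averages
#' duplicated (id, time) rows with a warning.
#'
#' @param path CSV file path.
#' @param id,time,outcome Column names in the file.
#' @param covariates Character vector of covariate columns to retain.
#' @return A canonicalized data frame with columns `id`, `time`, `y` and the
#'   covariates.
#' @export
read_long <- function(path, id = "id", time = "time", outcome = "y",
                      covariates = character()) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c(id, time, outcome, covariates)
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("unmapped columns: ", paste(miss, collapse = ", "))
  tvals <- suppressWarnings(as.numeric(df[[time]]))
  if (anyNA(tvals) && !all(is.na(df[[time]]) == is.na(tvals)))
    stop("non-numeric time values")
  out <- data.frame(id = as.character(df[[id]]), time = tvals,
                    y = as.numeric(df[[outcome]]))
  for (v in covariates) out[[v]] <- as.numeric(df[[v]])
  key <- paste(out$id, format(out$time, digits = 15))
  if (anyDuplicated(key)) {
    warning("duplicated (id, time) rows averaged")
    num <- setdiff(names(out), c("id", "time"))
    agg <- stats::aggregate(out[num], list(id = out$id, time = out$time),
                            mean, na.rm = TRUE)
    out <- agg[c("id", "time", num)]
  }
  out[order(out$id, out$time), , drop = FALSE]
}

serialize_fpca <- function(m) {
  list(basis = basis_to_table(m$basis), mean_coeffs = m$mean_coeffs,
       gamma = m$gamma, error_var = m$error_var, evalues = m$evalues,
       efuncs = m$efuncs, lambda_cov = m$lambda_cov)
}

deserialize_fpca <- function(s) {
  structure(
    list(basis = basis_from_table(as.data.frame(s$basis)),
         mean_coeffs = as.numeric(s$mean_coeffs),
         gamma = as.matrix(s$gamma), error_var = as.numeric(s$error_var),
         evalues = as.numeric(s$evalues), efuncs = as.matrix(s$efuncs),
         lambda_cov = as.numeric(s$lambda_cov)),
    class = "fpca_model")
}

#' Save a fitted model to a single JSON file
#'
#' Serializes everything needed to reproduce predictions bit-exactly (basis
#' knots, coefficients, variance components, covariate models).
#'
#' @param fit An `fcr_fit` or `amm_fit`.
#' @param path Output file path.
#' @export
save_fcr_fit <- function(fit, path) {
  s <- list(
    class = class(fit)[1], model = fit$model,
    basis = basis_to_table(fit$basis), theta = fit$theta,
    lambdas = fit$lambdas, cov_theta = fit$cov_theta, sigma2 = fit$sigma2,
    terms = fit$terms, invariant = fit$invariant, varying = fit$varying,
    selector = fit$selector, o = fit$o, N = fit$N, t_max = fit$t_max,
    columns = fit$columns,
    covariate_models = lapply(fit$covariate_models, serialize_fpca)
  )
  if (!is.null(fit$Gamma)) s$Gamma <- fit$Gamma
  if (!is.null(fit$Psi)) s$Psi <- fit$Psi
  if (!is.null(fit$cov_bayes)) s$cov_bayes <- fit$cov_bayes
  if (!is.null(fit$rand_basis)) s$rand_basis <- basis_to_table(fit$rand_basis)
  # I(17) = 17 significant digits: exact binary round-trip for doubles
  writeLines(jsonlite::toJSON(s, digits = I(17), auto_unbox = TRUE,
                              null = "null"), path)
  invisible(path)
}

#' Load a fitted model saved by [save_fcr_fit()]
#'
#' @param path JSON file path.
#' @return The reconstructed fit object.
#' @export
load_fcr_fit <- function(path) {
  s <- jsonlite::fromJSON(readLines(path), simplifyVector = TRUE)
  fit <- list(
    model = s$model, basis = basis_from_table(as.data.frame(s$basis)),
    theta = as.numeric(s$theta), lambdas = as.numeric(s$lambdas),
    cov_theta = as.matrix(s$cov_theta), sigma2 = as.numeric(s$sigma2),
    terms = as.character(s$terms),
    invariant = as.character(unlist(s$invariant)),
    varying = as.character(unlist(s$varying)),
    selector = s$selector, o = as.integer(s$o), N = as.integer(s$N),
    t_max = as.numeric(s$t_max), columns = as.list(s$columns),
    covariate_models = lapply(s$covariate_models, deserialize_fpca)
  )
  if (!is.null(s$Gamma)) fit$Gamma <- as.matrix(s$Gamma)
  if (!is.null(s$Psi)) fit$Psi <- as.matrix(s$Psi)
  if (!is.null(s$cov_bayes)) fit$cov_bayes <- as.matrix(s$cov_bayes)
  if (!is.null(s$rand_basis))
    fit$rand_basis <- basis_from_table(as.data.frame(s$rand_basis))
  class(fit) <- s$class
  fit
}

#' Export estimated coefficient functions as CSV
#'
#' Writes one row per (function, time) with the estimate, pointwise standard
#' error and 95% limits.
#'
#' @param fit A fitted model.
#' @param path Output CSV path.
#' @param t Evaluation grid (default 200 points over the basis domain).
#' @export
export_coefficients <- function(fit, path, t = NULL) {
  t <- t %||% seq(fit$basis$boundary[1], fit$basis$boundary[2],
                  length.out = 200)
  rows <- lapply(seq_along(fit$terms) - 1L, function(p) {
    cf <- coefficient_function(fit, p, t)
    cbind(fn = paste0("f", p), term = fit$terms[p + 1L], cf)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Export a prediction as CSV
#'
#' @param pred An `fcr_prediction`.
#' @param path Output CSV path.
#' @param id Optional subject identifier column value.
#' @export
export_prediction <- function(pred, path, id = NA_character_) {
  df <- data.frame(id = id, t = pred$t, y_hat = pred$y_hat, sd = pred$sd,
                   lo95 = pred$lo95, hi95 = pred$hi95,
                   cutoff = attr(pred, "cutoff"))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
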