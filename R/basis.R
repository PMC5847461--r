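#' B-spline basis with quantile-placed interior knots
#'
#' Constructs a B-spline basis on the range of the observed time points, with
#' interior knots placed at the empirical quantiles of the pooled unique
#' times. The number of basis functions is `n_interior + order`.
#'
#' @param times Numeric vector of observed time points (pooled over subjects).
#' @param n_interior Number of interior knots (>= 0).
#' @param order Spline order; 4 gives cubic B-splines (the default).
#' @return An object of class `fcr_basis` with fields `order`,
#'   `interior_knots`, `boundary` (length-2 numeric), and `c` (number of
#'   basis functions).
#' @examples
#' b <- fcr_basis(seq(0, 1, length.out = 50), n_interior = 3)
#' b$c  # 7 basis functions
#' @export
fcr_basis <- function(times, n_interior = 6L, order = 4L) {
  if (length(times) == 0L || !all(is.finite(times)))
    stop("'times' must be a nonempty vector of finite values")
  if (order < 2L) stop("'order' must be at least 2")
  if (n_interior < 0L) stop("'n_interior' must be nonnegative")
  ut <- sort(unique(as.numeric(times)))
  if (length(ut) < n_interior + 2L)
    stop("degenerate knots: need at least n_interior + 2 distinct time points")
  boundary <- range(ut)
  if (n_interior > 0L) {
    probs <- seq_len(n_interior) / (n_interior + 1)
    ik <- unname(stats::quantile(ut, probs = probs, type = 7))
    ik <- ik[ik > boundary[1] & ik < boundary[2]]
    if (anyDuplicated(ik)) {
      warning("duplicate interior knots collapsed; basis dimension reduced")
      ik <- unique(ik)
    }
  } else {
    ik <- numeric(0)
  }
  structure(
    list(order = as.integer(order), interior_knots = ik,
         boundary = boundary, c = length(ik) + as.integer(order)),
    class = "fcr_basis"
  )
}

# full knot vector with order-fold replicated boundary knots
full_knots <- function(basis) {
  c(rep(basis$boundary[1], basis$order), basis$interior_knots,
    rep(basis$boundary[2], basis$order))
}

#' Evaluate a B-spline basis
#'
#' Evaluates every basis function at the given times. Rows form a partition
#' of unity. Times outside the basis domain raise an error; excursions below
#' `1e-8` of the domain range are clamped as a floating-point guard.
#'
#' @param basis An `fcr_basis` object.
#' @param t Numeric vector of evaluation times.
#' @return A `length(t) x basis$c` matrix of basis values.
#' @export
eval_basis <- function(basis, t) {
  stopifnot(inherits(basis, "fcr_basis"))
  t <- as.numeric(t)
  if (length(t) == 0L) return(matrix(0, 0L, basis$c))
  rng <- basis$boundary
  tol <- 1e-8 * max(diff(rng), 1)
  if (any(t < rng[1] - tol | t > rng[2] + tol))
    stop("evaluation times outside basis domain [", rng[1], ", ", rng[2], "]")
  t <- pmin(pmax(t, rng[1]), rng[2])
  splines::splineDesign(full_knots(basis), t, ord = basis$order)
}

#' Difference penalty matrix
#'
#' Builds the o-th order difference operator `D` ((c-o) x c) and the penalty
#' `D'D` used to regularize adjacent B-spline coefficients. The null space of
#' `D'D` consists of polynomial sequences of degree < o in the coefficient
#' index, so `o = 2` (the default throughout) shrinks toward linear trends.
#'
#' @param c Number of basis coefficients.
#' @param o Order of the difference penalty (0 < o < c).
#' @return A list of class `fcr_penalty` with `D`, `matrix` (= `D'D`) and `o`.
#' @export
difference_penalty <- function(c, o = 2L) {
  c <- as.integer(c); o <- as.integer(o)
  if (o <= 0L || o >= c) stop("invalid difference order: need 0 < o < c")
  D <- diff(diag(c), differences = o)
  structure(list(D = D, matrix = crossprod(D), o = o, c = c),
            class = "fcr_penalty")
}

#' Export a basis as a plain table
#'
#' @param basis An `fcr_basis` object.
#' @return A data frame with one row per knot plus an attribute-free encoding
#'   (`what`, `value`) sufficient to reconstruct the basis bit-exactly.
#' @seealso [basis_from_table()]
#' @export
basis_to_table <- function(basis) {
  stopifnot(inherits(basis, "fcr_basis"))
  data.frame(
    what = c("order", "boundary_min", "boundary_max",
             rep("interior_knot", length(basis$interior_knots))),
    value = c(basis$order, basis$boundary, basis$interior_knots)
  )
}

#' Rebuild a basis from its plain-table export
#'
#' @param tab A data frame produced by [basis_to_table()].
#' @return An `fcr_basis` object.
#' @export
basis_from_table <- function(tab) {
  ord <- as.integer(tab$value[tab$what == "order"])
  bmin <- tab$value[tab$what == "boundary_min"]
  bmax <- tab$value[tab$what == "boundary_max"]
  ik <- tab$value[tab$what == "interior_knot"]
  structure(
    list(order = ord, interior_knots = as.numeric(ik),
         boundary = c(bmin, bmax), c = length(ik) + ord),
    class = "fcr_basis"
  )
}

#' @export
print.fcr_basis <- function(x, ...) {
  cat("B-spline basis: order", x$order, "with", length(x$interior_knots),
      "interior knots on [", x$boundary[1], ",", x$boundary[2], "], c =",
      x$c, "\n")
  invisible(x)
}

# Gram matrix G[k,l] = \int B_k(t) B_l(t) dt, exact via Gauss-Legendre(4)
# on each knot span (integrand is piecewise polynomial of degree <= 2*(order-1)).
basis_gram <- function(basis) {
  nodes <- c(-0.8611363115940526, -0.3399810435848563,
             0.3399810435848563, 0.8611363115940526)
  wts <- c(0.3478548451374538, 0.6521451548625461,
           0.6521451548625461, 0.3478548451374538)
  brk <- unique(c(basis$boundary[1], basis$interior_knots, basis$boundary[2]))
  G <- matrix(0, basis$c, basis$c)
  for (i in seq_len(length(brk) - 1L)) {
    a <- brk[i]; b <- brk[i + 1L]
    h <- (b - a) / 2
    x <- a + h * (nodes + 1)
    Bx <- eval_basis(basis, x)
    G <- G + h * crossprod(Bx * sqrt(wts), Bx * sqrt(wts))
  }
  (G + t(G)) / 2
}
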