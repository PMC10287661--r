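#' Cubic B-spline basis with curvature penalty
#'
#' Builds a cubic B-spline basis over the observed age span with interior knots
#' placed at quantiles of the distinct ages, together with a second-order
#' (divided) difference penalty on the coefficients. The divided differences are
#' taken with respect to the Greville abscissae of the basis, so the penalty
#' null space is exactly the linear functions \{1, t\}: as the smoothing
#' parameter grows without bound the fitted smooth degenerates to an ordinary
#' straight-line fit.
#'
#' @param ages numeric vector of ages (days) the basis will be used on.
#' @param K basis dimension (number of B-spline coefficients), at least 4.
#' @param range optional boundary span `c(lo, hi)` containing all ages; by
#'   default the observed age range. Supplying the full study span (e.g.
#'   `c(0, 810)`) lets fitted curves be evaluated at term birth and at the
#'   27-month ceiling even when no scan falls exactly there.
#' @return an object of class `spline_basis` with elements `knots` (full knot
#'   vector, boundary knots repeated 4 times), `K`, `range`, `greville`
#'   (Greville abscissae), `D` (second divided-difference matrix, (K-2) x K)
#'   and `S = t(D) %*% D` (penalty matrix).
#' @examples
#' b <- build_spline_basis(seq(0, 810, by = 30), K = 10)
#' rowSums(eval_basis(b, c(0, 100, 810)))  # partition of unity
#' @export
build_spline_basis <- function(ages, K = 10, range = NULL) {
  if (!is.numeric(ages) || !length(ages)) stop("'ages' must be a non-empty numeric vector")
  if (K < 4) stop("'K' must be at least 4 for a cubic basis")
  ua <- sort(unique(ages[is.finite(ages)]))
  if (length(ua) < K) {
    stop(sprintf("need at least %d distinct ages for K = %d, got %d",
                 K, K, length(ua)))
  }
  rng <- if (is.null(range)) base::range(ua) else as.numeric(range)
  if (rng[1] > ua[1] || rng[2] < ua[length(ua)])
    stop("'range' must contain all observed ages")
  n_int <- K - 4L
  interior <- if (n_int > 0L) {
    stats::quantile(ua, probs = seq_len(n_int) / (n_int + 1), names = FALSE, type = 7)
  } else numeric(0)
  knots <- c(rep(rng[1], 4L), interior, rep(rng[2], 4L))
  # Greville abscissae for cubic splines: means of 3 consecutive inner knots
  greville <- vapply(seq_len(K), function(j) mean(knots[(j + 1L):(j + 3L)]), 0)
  D <- divdiff2_matrix(greville)
  structure(
    list(knots = knots, K = K, range = rng, greville = greville,
         D = D, S = crossprod(D)),
    class = "spline_basis"
  )
}

# Second divided-difference matrix wrt abscissae x; rows annihilate 1 and x.
divdiff2_matrix <- function(x) {
  K <- length(x)
  D <- matrix(0, K - 2L, K)
  for (i in 2:(K - 1L)) {
    h0 <- x[i] - x[i - 1L]
    h1 <- x[i + 1L] - x[i]
    D[i - 1L, i - 1L] <- 1 / h0
    D[i - 1L, i] <- -(1 / h0 + 1 / h1)
    D[i - 1L, i + 1L] <- 1 / h1
  }
  # scale rows so the penalty approximates an integrated-curvature penalty
  w <- sqrt(2 / (x[3:K] - x[1:(K - 2L)]))
  D * w
}

#' Evaluate a spline basis (or its derivatives)
#'
#' @param basis a `spline_basis` from [build_spline_basis()].
#' @param t ages (days) inside the basis span.
#' @param deriv derivative order (0, 1 or 2).
#' @return numeric matrix, `length(t)` rows by `basis$K` columns.
#' @export
eval_basis <- function(basis, t, deriv = 0L) {
  stopifnot(inherits(basis, "spline_basis"))
  if (any(t < basis$range[1] - 1e-8 | t > basis$range[2] + 1e-8)) {
    stop(sprintf("ages outside the basis span [%g, %g]", basis$range[1], basis$range[2]))
  }
  t <- pmin(pmax(t, basis$range[1]), basis$range[2])
  splines::splineDesign(basis$knots, t, ord = 4L,
                        derivs = rep(as.integer(deriv), length(t)))
}

#' @export
print.spline_basis <- function(x, ...) {
  cat(sprintf("Cubic B-spline basis: K = %d over [%g, %g] days, %d interior knots\n",
              x$K, x$range[1], x$range[2], x$K - 4L))
  invisible(x)
}
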