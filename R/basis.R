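#' B-spline basis with equidistant interior knots
#'
#' Constructs the spline system used to represent the latent functional
#' features: `P` B-spline basis functions of a given order on a closed
#' interval, with boundary knots repeated `order` times and the `P - order`
#' interior knots placed on an equidistant grid. Equidistant knots are part of
#' the identifiability conditions for the mixed membership model, so the knot
#' vector is never user-supplied.
#'
#' @param domain Numeric length-2 vector `c(T0, T1)` with `T0 < T1`.
#' @param P Number of basis functions (`P >= order`).
#' @param order Spline order (polynomial degree + 1). Order 4 gives cubic
#'   splines, the usual smoothness level for functional data.
#'
#' @return An object of class `fmm_basis` with fields `domain`, `P`, `order`,
#'   `knots` (full knot vector) and `interior` (interior knots only).
#' @export
#' @examples
#' bs <- fmm_basis(c(0, 1), P = 8)
#' colSums(eval_basis(bs, seq(0, 1, length.out = 5)))  # partition of unity
fmm_basis <- function(domain, P, order = 4L) {
  stopifnot(is.numeric(domain), length(domain) == 2L, domain[1] < domain[2])
  P <- as.integer(P); order <- as.integer(order)
  if (order < 2L) abort("`order` must be at least 2.")
  if (P < order) abort(sprintf("`P` (%d) must be at least `order` (%d).", P, order))
  interior <- if (P > order) {
    seq(domain[1], domain[2], length.out = P - order + 2L)[-c(1L, P - order + 2L)]
  } else numeric(0)
  knots <- c(rep(domain[1], order), interior, rep(domain[2], order))
  structure(
    list(domain = as.numeric(domain), P = P, order = order,
         knots = knots, interior = interior),
    class = "fmm_basis"
  )
}

#' @export
print.fmm_basis <- function(x, ...) {
  cat(sprintf("<fmm_basis> P = %d, order = %d, domain = [%g, %g], %d interior knots\n",
              x$P, x$order, x$domain[1], x$domain[2], length(x$interior)))
  invisible(x)
}

#' Evaluate the basis design matrix
#'
#' Evaluates all `P` basis functions at the requested times. Column `j` of the
#' result is `B(t_j)`, so the matrix is the transpose of the usual n-by-P
#' spline design matrix. Evaluation at the right endpoint uses the left-limit
#' convention so the design is defined on the closed domain.
#'
#' @param basis An [fmm_basis()] object.
#' @param times Numeric vector of evaluation points, all inside the domain
#'   (endpoints included). Values outside the domain are an error: the basis
#'   does not extrapolate.
#'
#' @return A `P x length(times)` matrix.
#' @export
eval_basis <- function(basis, times) {
  stopifnot(inherits(basis, "fmm_basis"), is.numeric(times))
  if (length(times) == 0L) return(matrix(0, basis$P, 0L))
  if (any(!is.finite(times))) abort("`times` must be finite.")
  eps <- 1e-12 * max(1, abs(basis$domain))
  if (any(times < basis$domain[1] - eps) || any(times > basis$domain[2] + eps)) {
    bad <- which(times < basis$domain[1] - eps | times > basis$domain[2] + eps)
    abort(sprintf(
      "%d evaluation point(s) outside the basis domain [%g, %g] (first: t = %g). No extrapolation.",
      length(bad), basis$domain[1], basis$domain[2], times[bad[1]]))
  }
  t_clamped <- pmin(pmax(times, basis$domain[1]), basis$domain[2])
  D <- splines::splineDesign(basis$knots, t_clamped, ord = basis$order,
                             outer.ok = FALSE)
  t(D)
}

#' First-difference penalty matrix
#'
#' Returns the (P-1) x P first-difference operator whose quadratic form
#' `|| D v ||^2 = sum_p (v_p - v_{p+1})^2` defines the first-order random walk
#' smoothing prior on basis coefficients. `D v = 0` exactly when `v` is
#' constant.
#'
#' @param basis An [fmm_basis()] object (or an integer P).
#' @return A `(P-1) x P` matrix.
#' @export
difference_penalty <- function(basis) {
  P <- if (inherits(basis, "fmm_basis")) basis$P else as.integer(basis)
  if (P < 2L) abort("Need P >= 2 for a first-difference penalty.")
  D <- matrix(0, P - 1L, P)
  for (p in seq_len(P - 1L)) {
    D[p, p] <- 1
    D[p, p + 1L] <- -1
  }
  D
}
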