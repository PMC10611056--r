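#' Locate interior extrema of a signal
#'
#' An interior sample is a maximum when it is strictly greater than its
#' nearest distinct neighbours on both sides (and symmetrically for minima).
#' A run of equal samples (plateau) counts as a single extremum placed at the
#' run's first index; boundary samples are never extrema. A constant signal
#' therefore has empty extrema sets, which is a valid (not an error) outcome.
#'
#' @param signal A `signal_channel` or numeric vector, length >= 3, finite.
#' @return An object of class `extrema_set`: a list with integer vectors
#'   `max_positions`, `min_positions` (0-based sample indices, sorted
#'   ascending) and numeric vectors `max_values`, `min_values`.
#' @examples
#' find_extrema(c(0, 1, 0))
#' @export
find_extrema <- function(signal) {
  x <- as_samples(signal, min_len = 3L)
  ex <- cpp_find_extrema(x)
  structure(list(max_positions = ex$max_positions,
                 max_values = x[ex$max_positions + 1L],
                 min_positions = ex$min_positions,
                 min_values = x[ex$min_positions + 1L]),
            class = "extrema_set")
}

#' @export
print.extrema_set <- function(x, ...) {
  cat("<extrema_set>", length(x$max_positions), "maxima,",
      length(x$min_positions), "minima\n")
  invisible(x)
}

#' Solve a tridiagonal linear system
#'
#' Thomas-algorithm forward elimination and back substitution without
#' pivoting. Intended for the strictly diagonally dominant systems arising
#' from natural cubic-spline construction; a zero pivot raises an error
#' naming the offending row.
#'
#' @param sub Sub-diagonal, length `n - 1`.
#' @param diagonal Main diagonal, length `n`.
#' @param super Super-diagonal, length `n - 1`.
#' @param rhs Right-hand side, length `n`.
#' @return The solution vector `x` with `A x = rhs`.
#' @examples
#' solve_tridiagonal(numeric(0), 2, numeric(0), 6)  # 1x1 system -> 3
#' @export
solve_tridiagonal <- function(sub, diagonal, super, rhs) {
  n <- length(diagonal)
  if (n < 1L) stop("empty system")
  if (length(sub) != n - 1L || length(super) != n - 1L)
    stop("sub/super diagonals must have length n - 1 = ", n - 1L)
  if (length(rhs) != n) stop("rhs must have length n = ", n)
  cpp_solve_tridiagonal(as.numeric(sub), as.numeric(diagonal),
                        as.numeric(super), as.numeric(rhs))
}

#' Natural cubic-spline coefficients
#'
#' Builds the piecewise cubic through the given knots with continuous first
#' and second derivatives at interior knots and zero second derivative at the
#' end knots (natural boundary). The interior second derivatives come from a
#' strictly diagonally dominant tridiagonal system solved with
#' [solve_tridiagonal()]. With two knots the result is the straight line
#' through them.
#'
#' @param knot_positions Strictly increasing numeric positions (sample
#'   indices; fractional positions from boundary mirroring are allowed).
#' @param knot_values Knot ordinates, same length.
#' @return An object of class `spline_coefficients`: list with `knots` and a
#'   `(length(knots) - 1) x 4` matrix `coefficients` whose columns are the
#'   constant, linear, quadratic and cubic terms of each segment, expanded
#'   about the segment's left knot.
#' @export
natural_spline_coefficients <- function(knot_positions, knot_values) {
  t <- as.numeric(knot_positions)
  y <- as.numeric(knot_values)
  if (length(t) < 2L)
    stop("degenerate input: a spline needs at least 2 knots, got ", length(t))
  if (length(y) != length(t))
    stop("knot positions and values differ in length")
  if (any(diff(t) <= 0)) stop("knot positions must be strictly increasing")
  structure(cpp_spline_coefficients(t, y), class = "spline_coefficients")
}

#' Evaluate a fitted spline
#'
#' @param coeffs A `spline_coefficients` object from
#'   [natural_spline_coefficients()].
#' @param query_positions Positions at which to evaluate.
#' @param boundary_policy How to treat positions outside the knot span:
#'   `"extend"` evaluates the first/last segment's cubic beyond its knot
#'   (so a linear spline extrapolates linearly), `"nearest"` clamps to the
#'   end-knot values.
#' @return Numeric vector of interpolated values.
#' @export
evaluate_spline <- function(coeffs, query_positions,
                            boundary_policy = c("extend", "nearest")) {
  boundary_policy <- match.arg(boundary_policy)
  stopifnot(inherits(coeffs, "spline_coefficients"))
  cpp_eval_spline(coeffs$knots, coeffs$coefficients,
                  as.numeric(query_positions),
                  if (boundary_policy == "extend") 0L else 1L)
}

#' Upper and lower signal envelopes
#'
#' Fits natural cubic splines through the maxima (upper) and minima (lower)
#' of a signal and evaluates both at every sample position. To limit end
#' effects, the default policy mirrors the two extrema nearest each end
#' across the signal boundary before fitting, so the spline span covers the
#' whole signal.
#'
#' @param signal A `signal_channel` or numeric vector.
#' @param extrema Optional `extrema_set`; computed with [find_extrema()]
#'   when missing.
#' @param boundary Either `"mirror"` (default end-effect mitigation) or
#'   `"none"` (splines through the raw extrema, end segments extrapolated).
#' @return An object of class `envelope_pair`: list with numeric vectors
#'   `upper` and `lower`, both of the signal's length, or an error of class
#'   `iceemdan_monotonic` when fewer than 2 maxima or 2 minima exist (the
#'   EMD stop condition).
#' @export
build_envelope_pair <- function(signal, extrema = NULL,
                                boundary = c("mirror", "none")) {
  boundary <- match.arg(boundary)
  x <- as_samples(signal, min_len = 4L)
  if (is.null(extrema)) extrema <- find_extrema(x)
  env <- cpp_envelope_pair(x, extrema$max_positions, extrema$min_positions,
                           boundary == "mirror")
  if (!isTRUE(env$ok)) {
    cond <- structure(
      class = c("iceemdan_monotonic", "error", "condition"),
      list(message = sprintf(
             "signal has %d maxima and %d minima; envelope needs >= 2 of each",
             length(extrema$max_positions), length(extrema$min_positions)),
           call = sys.call(-1)))
    stop(cond)
  }
  structure(list(upper = env$upper, lower = env$lower),
            class = "envelope_pair")
}

#' Mean of an envelope pair
#'
#' @param pair An `envelope_pair` (or any list with numeric `upper` and
#'   `lower` of equal length).
#' @return Elementwise `(upper + lower) / 2`.
#' @export
mean_envelope <- function(pair) {
  if (length(pair$upper) != length(pair$lower))
    stop("upper and lower envelopes differ in length")
  (pair$upper + pair$lower) / 2
}
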