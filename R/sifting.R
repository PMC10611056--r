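#' Sifting configuration
#'
#' Controls the inner loop that refines a candidate intrinsic mode function
#' (IMF). The default is a fixed number of sifting iterations, which keeps
#' the operation count identical across realizations and makes ensemble runs
#' exactly reproducible. A Cauchy-style threshold mode is available: sifting
#' stops once the relative squared change of the candidate between
#' iterations falls below `threshold`, with `n_iterations` as the cap.
#'
#' @param n_iterations Number of sifting passes S (fixed mode) or the
#'   iteration cap (threshold mode). Must be >= 1.
#' @param stop_mode `"fixed"` (default) or `"threshold"`.
#' @param threshold Relative squared-change tolerance for threshold mode.
#' @param precision `"double"` (default) or `"single"`; single rounds the
#'   working arrays to 32-bit float after every update, emulating an FP32
#'   pipeline.
#' @return An object of class `sift_config`.
#' @export
sift_config <- function(n_iterations = 10L,
                        stop_mode = c("fixed", "threshold"),
                        threshold = 0.2,
                        precision = c("double", "single")) {
  stop_mode <- match.arg(stop_mode)
  precision <- match.arg(precision)
  n_iterations <- as.integer(n_iterations)
  if (is.na(n_iterations) || n_iterations < 1L)
    stop("n_iterations must be a positive integer")
  if (stop_mode == "threshold" && (!is.finite(threshold) || threshold <= 0))
    stop("threshold must be a positive number")
  structure(list(n_iterations = n_iterations, stop_mode = stop_mode,
                 threshold = threshold, precision = precision),
            class = "sift_config")
}

sift_args <- function(config) {
  list(S = config$n_iterations,
       stop_mode = if (config$stop_mode == "threshold") 1L else 0L,
       tol = config$threshold,
       fp32 = identical(config$precision, "single"))
}

#' Extract a candidate IMF by sifting
#'
#' Applies rounds of (extrema detection, envelope construction, envelope-mean
#' subtraction) to a working copy of the signal and returns the final working
#' copy as the candidate IMF. If at any round the working copy has fewer than
#' 2 maxima or 2 minima, it is returned as-is with the `monotonic` attribute
#' set — a flagged, valid outcome consumed by the EMD stop logic.
#'
#' @param signal A `signal_channel` or numeric vector.
#' @param config A [sift_config()].
#' @return Numeric vector (the candidate mode) with attributes `monotonic`
#'   (logical) and `iterations` (sifting passes actually performed).
#' @export
sift <- function(signal, config = sift_config()) {
  x <- as_samples(signal, min_len = 4L)
  a <- sift_args(config)
  res <- cpp_sift(x, a$S, a$stop_mode, a$tol, a$fp32)
  structure(res$mode, monotonic = res$monotonic, iterations = res$iterations)
}

#' Local mean of a signal
#'
#' The local-mean operator M(x) returns the midline left after removing the
#' fully sifted first mode: `M(x) = x - sift(x)`. The identity
#' `sift(x) + local_mean(x) == x` holds exactly by construction.
#'
#' @inheritParams sift
#' @return Numeric vector of the same length as the input.
#' @export
local_mean <- function(signal, config = sift_config()) {
  x <- as_samples(signal, min_len = 4L)
  m <- sift(x, config)
  x - as.numeric(m)
}

#' Empirical mode decomposition
#'
#' Repeatedly sifts the running residue to extract intrinsic mode functions,
#' subtracting each mode as it is found. Extraction stops when `max_modes`
#' modes have been produced or when the residue has fewer than 2 maxima or
#' 2 minima (no further oscillation to extract). The decomposition is
#' complete: the modes plus the final residue sum back to the input up to
#' float rounding.
#'
#' @param signal A `signal_channel` or numeric vector.
#' @param max_modes Maximum number of modes K to extract.
#' @param config A [sift_config()].
#' @return An `emd_decomposition`: list with `modes` (a `n_modes x N`
#'   matrix, one mode per row, possibly 0-row), `residue` (length-N vector)
#'   and `n_modes`.
#' @examples
#' x <- sin(2 * pi * 0.05 * 0:499) + 0.002 * (0:499)
#' d <- emd(x, max_modes = 4)
#' max(abs(colSums(d$modes) + d$residue - x))  # completeness
#' @export
emd <- function(signal, max_modes = 12L, config = sift_config()) {
  x <- as_samples(signal, min_len = 4L)
  if (max_modes < 1L) stop("max_modes must be >= 1")
  a <- sift_args(config)
  res <- cpp_emd(x, as.integer(max_modes), a$S, a$stop_mode, a$tol, a$fp32)
  new_decomposition(res$modes, res$residue, signal = signal)
}

new_decomposition <- function(modes, residue, signal = NULL,
                              class = character()) {
  structure(list(modes = modes, residue = as.numeric(residue),
                 n_modes = nrow(modes),
                 sampling_rate = sampling_rate_of(signal)),
            class = c(class, "emd_decomposition"))
}

#' @export
print.emd_decomposition <- function(x, ...) {
  cat("<", class(x)[1L], "> ", x$n_modes, " modes, N = ",
      length(x$residue), "\n", sep = "")
  invisible(x)
}

#' Reconstruct the input of a decomposition
#'
#' @param decomposition An `emd_decomposition` or `iceemdan_result`.
#' @return Sum of all modes plus the residue.
#' @export
reconstruct <- function(decomposition) {
  if (decomposition$n_modes == 0L) return(decomposition$residue)
  colSums(decomposition$modes) + decomposition$residue
}
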