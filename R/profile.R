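#' Per-stage timing of the sifting pipeline
#'
#' When enabled, the compiled core accumulates wall-clock time spent in each
#' stage of the sifting process: extrema detection, the tridiagonal solve,
#' spline-coefficient assembly, interpolation, the envelope mean, and the
#' residue update. Profiling is off by default; the counters are
#' process-global.
#'
#' @param enable Switch stage timing on or off.
#' @return `sifting_profile()` returns a named numeric vector of seconds
#'   per stage.
#' @export
profile_sifting <- function(enable = TRUE) {
  cpp_profile_enable(isTRUE(enable))
  invisible(enable)
}

#' @rdname profile_sifting
#' @export
sifting_profile <- function() cpp_profile_read()

#' @rdname profile_sifting
#' @export
reset_sifting_profile <- function() {
  cpp_profile_reset()
  invisible(NULL)
}
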