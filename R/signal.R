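#' Construct a signal channel
#'
#' A `signal_channel` is a plain numeric vector of samples with optional
#' sampling-rate and label metadata. All decomposition functions accept
#' either a `signal_channel` or a bare numeric vector.
#'
#' @param samples Numeric vector of finite amplitudes. Decomposition
#'   functions require at least 4 samples; shorter channels can be read and
#'   written but not decomposed.
#' @param sampling_rate Optional sampling rate in Hz.
#' @param label Optional channel label.
#' @return A numeric vector of class `signal_channel` with attributes
#'   `sampling_rate` and `label`.
#' @examples
#' ch <- signal_channel(sin(2 * pi * 0.05 * 0:199), sampling_rate = 250)
#' @export
signal_channel <- function(samples, sampling_rate = NULL, label = NULL) {
  samples <- as.numeric(samples)
  if (length(samples) < 1L)
    stop("a signal channel needs at least 1 sample")
  if (!all(is.finite(samples)))
    stop("signal contains non-finite samples (NA/NaN/Inf)")
  structure(samples,
            sampling_rate = sampling_rate,
            label = label,
            class = "signal_channel")
}

#' @export
print.signal_channel <- function(x, ...) {
  fs <- attr(x, "sampling_rate")
  lab <- attr(x, "label")
  cat("<signal_channel>", length(x), "samples",
      if (!is.null(fs)) paste0("@ ", fs, " Hz") else "",
      if (!is.null(lab)) paste0("[", lab, "]") else "", "\n")
  invisible(x)
}

# strip class/attributes; validate finiteness for internal use
as_samples <- function(x, min_len = 3L, arg = "signal") {
  v <- as.numeric(x)
  if (length(v) < min_len)
    stop(arg, " must have at least ", min_len, " samples")
  if (anyNA(v) || !all(is.finite(v)))
    stop(arg, " contains non-finite samples (NA/NaN/Inf)")
  v
}

sampling_rate_of <- function(x, default = NULL) {
  fs <- attr(x, "sampling_rate")
  if (is.null(fs)) default else fs
}
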