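#' Similarity index between two signals
#'
#' The normalized covariance `|cov(x, y)| / sqrt(var(x) var(y))`, i.e. the
#' absolute Pearson correlation of the two waveforms. The absolute value
#' maps the index onto [0, 1], where 1 means identical shape up to scale and
#' sign; mode polarity from a decomposition is sign-ambiguous, so the raw
#' signed value is available via `signed = TRUE`.
#'
#' @param x,y Numeric vectors of equal length >= 2, neither constant.
#' @param signed Return the signed value in [-1, 1] instead.
#' @return A number in [0, 1] (or [-1, 1] when `signed`).
#' @export
similarity_index <- function(x, y, signed = FALSE) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("inputs differ in length")
  if (length(x) < 2L) stop("inputs must have length >= 2")
  if (var(x) == 0 || var(y) == 0)
    stop("similarity index is undefined for a constant input (zero variance)")
  rho <- cov(x, y) / sqrt(var(x) * var(y))
  if (signed) rho else abs(rho)
}

#' Relative reconstruction error of a decomposition
#'
#' Measures completeness: `max |original - (sum of modes + residue)|`
#' relative to `max |original|`. A decomposition produced by [emd()],
#' [eemd()] or [iceemdan()] reconstructs its input up to float rounding, so
#' this is at the 1e-15 level; values above ~1e-9 indicate a broken
#' decomposition. For an all-zero original the absolute error is returned.
#'
#' @param original The decomposed signal.
#' @param decomposition An `emd_decomposition` or `iceemdan_result`.
#' @return A nonnegative number.
#' @export
reconstruction_error <- function(original, decomposition) {
  x <- as.numeric(original)
  if (length(x) != length(decomposition$residue))
    stop("signal and decomposition lengths differ")
  err <- max(abs(x - reconstruct(decomposition)))
  denom <- max(abs(x))
  if (denom == 0) err else err / denom
}

#' IMF property check
#'
#' An intrinsic mode function has extrema and zero-crossing counts differing
#' by at most one and a near-zero local mean. This reports those quantities
#' for a candidate mode: the number of interior extrema, the number of
#' strict sign changes, their absolute difference, and the RMS of the mode's
#' envelope mean (NA when fewer than 2 maxima or 2 minima exist, where
#' envelopes are undefined).
#'
#' @param mode Numeric vector.
#' @return An object of class `imf_validity`: list with `n_extrema`,
#'   `n_zero_crossings`, `extrema_zero_crossing_gap`, `mean_envelope_rms`.
#' @export
imf_validity <- function(mode) {
  x <- as.numeric(mode)
  ex <- cpp_find_extrema(x)
  n_ext <- length(ex$max_positions) + length(ex$min_positions)
  s <- sign(x)
  s <- s[s != 0]
  n_zc <- if (length(s) > 1L) sum(diff(s) != 0) else 0L
  rms <- NA_real_
  if (length(ex$max_positions) >= 2L && length(ex$min_positions) >= 2L) {
    env <- cpp_envelope_pair(x, ex$max_positions, ex$min_positions, TRUE)
    m <- (env$upper + env$lower) / 2
    rms <- sqrt(mean(m^2))
  }
  structure(list(n_extrema = n_ext, n_zero_crossings = as.integer(n_zc),
                 extrema_zero_crossing_gap = abs(n_ext - as.integer(n_zc)),
                 mean_envelope_rms = rms),
            class = "imf_validity")
}

#' Match decomposition modes to reference components
#'
#' For each reference waveform, finds the single extracted mode maximizing
#' the [similarity_index()]; ties go to the lower mode index. This is how a
#' decomposition of a synthetic signal is scored against its known
#' constituent components.
#'
#' @param decomposition An `emd_decomposition` or `iceemdan_result` with at
#'   least one mode.
#' @param references List of numeric vectors (ground-truth components).
#' @return An object of class `similarity_report`: a data frame `pairs`
#'   with columns `reference`, `mode`, `similarity`, plus
#'   `mean_similarity`.
#' @export
match_modes <- function(decomposition, references) {
  if (!is.list(references)) references <- list(references)
  if (decomposition$n_modes < 1L) stop("decomposition has no modes")
  if (length(references) < 1L) stop("no reference components given")
  pairs <- do.call(rbind, lapply(seq_along(references), function(j) {
    ref <- as.numeric(references[[j]])
    rho <- vapply(seq_len(decomposition$n_modes), function(k)
      similarity_index(decomposition$modes[k, ], ref), numeric(1))
    best <- which.max(rho)  # which.max takes the first (lowest) on ties
    data.frame(reference = j, mode = best, similarity = rho[best])
  }))
  structure(list(pairs = pairs,
                 mean_similarity = mean(pairs$similarity)),
            class = "similarity_report")
}

#' @export
print.similarity_report <- function(x, ...) {
  cat("<similarity_report>\n")
  print(x$pairs, row.names = FALSE)
  cat("mean similarity:", format(x$mean_similarity, digits = 6), "\n")
  invisible(x)
}

#' Serialize a similarity report to JSON
#'
#' @param report A `similarity_report`.
#' @return A JSON string.
#' @export
similarity_report_json <- function(report) {
  jsonlite::toJSON(list(pairs = report$pairs,
                        mean_similarity = report$mean_similarity),
                   auto_unbox = TRUE, digits = NA)
}

#' Dominant frequency by zero-padded FFT
#'
#' Estimates the dominant frequency of a (windowed) signal as the location
#' of the magnitude-spectrum peak of a zero-padded FFT. Zero padding refines
#' the frequency grid (peak interpolation), giving sub-bin resolution of the
#' carrier of a narrow-band mode.
#'
#' @param x Numeric vector.
#' @param sampling_rate Sampling rate in Hz.
#' @param n_fft Transform length; defaults to the smallest power of two
#'   giving at least 4x padding and a grid no coarser than 0.25 Hz.
#' @return Peak frequency in Hz.
#' @export
dominant_frequency <- function(x, sampling_rate, n_fft = NULL) {
  x <- as.numeric(x)
  if (is.null(n_fft)) {
    n_min <- max(4L * length(x), ceiling(sampling_rate / 0.25))
    n_fft <- 2^ceiling(log2(n_min))
  }
  spec <- Mod(fft(c(x - mean(x), numeric(n_fft - length(x)))))
  half <- seq_len(n_fft %/% 2 + 1L)
  peak <- which.max(spec[half])
  (peak - 1L) * sampling_rate / n_fft
}
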