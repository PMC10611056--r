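# Per-realization RNG streams: realization i always draws from a seed
# derived from (master seed, i), so row i of a batch is the same whatever
# the batch size or evaluation order. The derivation stays below 2^31 - 1.
derive_seed <- function(seed, i) {
  m <- 2147483647
  as.integer((abs(as.numeric(seed)) %% m + as.numeric(i) * 2654435761) %% m)
}

noise_realization <- function(seed, i, n) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(derive_seed(seed, i))
  rnorm(n)
}

#' Intermittent dual-tone test signal
#'
#' The 1000-sample synthetic signal used throughout validation: a fast
#' sinusoid `s1` at normalized frequency 0.255 cycles/sample that is nonzero
#' only on a 250-sample window in the second half of the record, plus a slow
#' sinusoid `s2` at 0.065 cycles/sample spanning the whole record. In 1-based
#' sample indices n = 1..1000,
#' `s1[n] = sin(2 pi 0.255 (n - 501))` for `501 <= n <= 750` (0 elsewhere)
#' and `s2[n] = sin(2 pi 0.065 (n - 1))`; the composite is `s = s1 + s2`.
#' At the nominal 1 kHz sampling rate the carriers sit at 255 Hz and 65 Hz.
#' The intermittency of `s1` makes the signal a standard probe for mode
#' mixing.
#'
#' @return An object of class `dual_tone_fixture`: list with `s` (the
#'   composite as a `signal_channel` at 1000 Hz), `s1`, `s2` (component
#'   vectors), `active_window` (1-based index range of the `s1` burst) and
#'   `sampling_rate`.
#' @examples
#' dt <- make_dual_tone()
#' stopifnot(all(dt$s == dt$s1 + dt$s2))
#' @export
make_dual_tone <- function() {
  n <- 1:1000
  s1 <- ifelse(n >= 501 & n <= 750, sin(2 * pi * 0.255 * (n - 501)), 0)
  s2 <- sin(2 * pi * 0.065 * (n - 1))
  s <- s1 + s2
  structure(list(s = signal_channel(s, sampling_rate = 1000,
                                    label = "dual_tone"),
                 s1 = s1, s2 = s2,
                 active_window = c(501L, 750L),
                 sampling_rate = 1000),
            class = "dual_tone_fixture")
}

#' Seeded Gaussian noise realizations
#'
#' Draws I rows of N zero-mean unit-variance Gaussian samples. Row `i` comes
#' from its own derived stream, so the first rows of an I = 10 batch equal
#' the first rows of an I = 100 batch under the same seed.
#'
#' @param n_realizations Number of rows I.
#' @param n_samples Row length N.
#' @param seed Master seed.
#' @return I x N numeric matrix.
#' @export
gaussian_noise_matrix <- function(n_realizations, n_samples, seed) {
  stopifnot(n_realizations >= 1L, n_samples >= 1L)
  out <- matrix(0, n_realizations, n_samples)
  for (i in seq_len(n_realizations))
    out[i, ] <- noise_realization(seed, i, n_samples)
  out
}

#' Multichannel EEG-like surrogate
#'
#' Generates channels as sums of amplitude-modulated band-limited sinusoids
#' at the conventional EEG rhythm centers plus 1/f (pink) background noise.
#' This is a plumbing fixture for end-to-end tests of multichannel file IO
#' and the command-line interface, not a biophysical EEG model.
#'
#' @param n_channels Number of channels.
#' @param n_samples Samples per channel.
#' @param sampling_rate Sampling rate in Hz.
#' @param band_amplitudes Named amplitudes of the delta (2 Hz), theta
#'   (6 Hz), alpha (10 Hz) and beta (20 Hz) components.
#' @param noise_amplitude Amplitude of the pink-noise background.
#' @param seed Master seed; channel c uses its own derived stream.
#' @return List of `signal_channel`s, labelled `ch1..chC`.
#' @export
make_synthetic_eeg <- function(n_channels = 4L, n_samples = 2048L,
                               sampling_rate = 256,
                               band_amplitudes = c(delta = 1.5, theta = 1.0,
                                                   alpha = 2.0, beta = 0.5),
                               noise_amplitude = 0.5, seed = 42L) {
  stopifnot(n_channels >= 1L, n_samples >= 16L)
  centers <- c(delta = 2, theta = 6, alpha = 10, beta = 20)
  t <- (0:(n_samples - 1L)) / sampling_rate
  lapply(seq_len(n_channels), function(ch) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(derive_seed(seed, 7919L + ch))
    x <- numeric(n_samples)
    for (b in names(centers)) {
      amp <- if (b %in% names(band_amplitudes)) band_amplitudes[[b]] else 0
      if (amp == 0) next
      # slow random amplitude modulation (waxing/waning rhythm)
      mod_f <- runif(1, 0.05, 0.3)
      phase <- runif(2, 0, 2 * pi)
      env <- 0.6 + 0.4 * sin(2 * pi * mod_f * t + phase[1])
      x <- x + amp * env * sin(2 * pi * centers[[b]] * t + phase[2])
    }
    if (noise_amplitude > 0)
      x <- x + noise_amplitude * pink_noise(n_samples)
    signal_channel(x, sampling_rate = sampling_rate,
                   label = paste0("ch", ch))
  })
}

# 1/f-amplitude noise via spectral shaping of white Gaussian noise,
# normalized to unit variance. Uses the current RNG state.
pink_noise <- function(n) {
  w <- rnorm(n)
  spec <- fft(w)
  f <- c(1, seq_len(n - 1))  # guard DC
  f <- pmin(f, n - f + 1)    # two-sided frequency magnitude
  spec <- spec / sqrt(f)
  x <- Re(fft(spec, inverse = TRUE)) / n
  as.numeric((x - mean(x)) / sd_pop(x))
}
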