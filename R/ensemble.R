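#' Ensemble decomposition configuration
#'
#' Collects every tunable of the ensemble algorithms: the number of noise
#' realizations I, the maximum mode count K, the sifting configuration, the
#' noise strength, the master seed and the rule used to scale the injected
#' noise modes.
#'
#' @param n_realizations Number of signal-plus-noise realizations I.
#' @param max_modes Maximum number of modes K to extract.
#' @param sift A [sift_config()].
#' @param noise_strength Nonnegative noise scale factor controlling the
#'   signal-to-added-noise ratio (0 disables noise entirely).
#' @param seed Master seed; realization `i` draws from an independently
#'   derived stream so its noise does not depend on I or evaluation order.
#' @param beta_rule `"residue-std"` scales the level-k noise mode by
#'   `noise_strength * sd(residue)` (population standard deviation);
#'   `"normalized-first-mode"` additionally divides by the standard
#'   deviation of the injected noise mode, so the noise strength is
#'   interpreted relative to the noise mode's own amplitude.
#' @param noise_tensor `"precompute"` extracts and stores all K x I x N
#'   noise modes up front; `"stream"` extracts one mode level at a time,
#'   bounding memory at I x N, with bit-identical results.
#' @return An object of class `ensemble_config`.
#' @export
ensemble_config <- function(n_realizations = 500L,
                            max_modes = 12L,
                            sift = sift_config(10L),
                            noise_strength = 0.2,
                            seed = 42L,
                            beta_rule = c("residue-std", "normalized-first-mode"),
                            noise_tensor = c("precompute", "stream")) {
  beta_rule <- match.arg(beta_rule)
  noise_tensor <- match.arg(noise_tensor)
  n_realizations <- as.integer(n_realizations)
  max_modes <- as.integer(max_modes)
  if (is.na(n_realizations) || n_realizations < 1L)
    stop("n_realizations must be a positive integer")
  if (is.na(max_modes) || max_modes < 1L)
    stop("max_modes must be a positive integer")
  if (!is.finite(noise_strength) || noise_strength < 0)
    stop("noise_strength must be a nonnegative number")
  stopifnot(inherits(sift, "sift_config"))
  structure(list(n_realizations = n_realizations, max_modes = max_modes,
                 sift = sift, noise_strength = noise_strength,
                 seed = as.integer(seed), beta_rule = beta_rule,
                 noise_tensor = noise_tensor),
            class = "ensemble_config")
}

# population (divide-by-n) standard deviation
sd_pop <- function(x) sqrt(mean((x - mean(x))^2))

#' Noise-mode amplitude beta
#'
#' Returns the amplitude applied to the injected noise mode at one
#' ICEEMDAN level: `noise_strength * sd(residue)` with the population
#' standard deviation (the `"residue-std"` rule), optionally divided by the
#' standard deviation of the corresponding noise mode
#' (`"normalized-first-mode"`).
#'
#' @param residue The current residue vector.
#' @param noise_strength Nonnegative scale factor.
#' @param beta_rule See [ensemble_config()].
#' @param noise_mode_std Standard deviation of the noise mode being
#'   injected; required by the normalized rule.
#' @return A single nonnegative number.
#' @export
noise_amplitude <- function(residue, noise_strength,
                            beta_rule = c("residue-std", "normalized-first-mode"),
                            noise_mode_std = NULL) {
  beta_rule <- match.arg(beta_rule)
  if (length(residue) == 0L) stop("empty residue")
  beta <- noise_strength * sd_pop(residue)
  if (beta_rule == "normalized-first-mode") {
    if (is.null(noise_mode_std))
      stop("the normalized-first-mode rule requires noise_mode_std")
    beta <- if (noise_mode_std > 0) beta / noise_mode_std else 0
  }
  beta
}

#' Build the batch of signal-plus-noise realizations
#'
#' Row `i` of the result is `residue + beta * noise_modes[i, ]`.
#'
#' @param residue Length-N residue vector.
#' @param noise_modes I x N matrix: one precomputed noise mode per
#'   realization.
#' @param beta Noise amplitude from [noise_amplitude()].
#' @return An I x N matrix (a realization batch).
#' @export
make_realizations <- function(residue, noise_modes, beta) {
  if (!is.matrix(noise_modes) || ncol(noise_modes) != length(residue))
    stop("noise_modes must be an I x ", length(residue), " matrix")
  sweep(beta * noise_modes, 2L, residue, "+")
}

#' Local means of a realization batch
#'
#' Applies the local-mean operator M to every row. Rows are processed with
#' the same scalar kernel as [local_mean()], so the batch result is
#' bit-identical to a per-row loop.
#'
#' @param batch I x N matrix of realizations.
#' @param config A [sift_config()].
#' @return I x N matrix of local means.
#' @export
batch_local_mean <- function(batch, config = sift_config()) {
  if (!is.matrix(batch)) batch <- matrix(batch, nrow = 1L)
  if (anyNA(batch) || !all(is.finite(batch)))
    stop("batch contains non-finite values")
  a <- sift_args(config)
  cpp_batch_local_mean(batch, a$S, a$stop_mode, a$tol, a$fp32)
}

#' Average across realizations
#'
#' @param matrix I x N matrix.
#' @return Columnwise arithmetic mean (length-N vector).
#' @export
ensemble_average <- function(matrix) {
  if (!is.matrix(matrix)) matrix <- base::matrix(matrix, nrow = 1L)
  colMeans(matrix)
}

# --- noise-mode machinery -------------------------------------------------

#' Precompute the noise-mode tensor
#'
#' Draws I zero-mean unit-variance Gaussian noise realizations from the
#' seeded per-realization streams, decomposes each with EMD, and stores the
#' first K modes in a K x I x N tensor (realizations yielding fewer than K
#' modes are zero-padded). Entry `[k, i, ]` is the k-th mode of noise
#' realization i, injected at ICEEMDAN level k.
#'
#' @param config An [ensemble_config()].
#' @param n_samples Signal length N.
#' @return An object of class `noise_mode_tensor` wrapping the K x I x N
#'   array.
#' @export
precompute_noise_modes <- function(config, n_samples) {
  stopifnot(inherits(config, "ensemble_config"))
  I <- config$n_realizations
  K <- config$max_modes
  a <- sift_args(config$sift)
  values <- array(0, dim = c(K, I, n_samples))
  for (i in seq_len(I)) {
    w <- noise_realization(config$seed, i, n_samples)
    d <- cpp_emd(w, K, a$S, a$stop_mode, a$tol, a$fp32)
    if (d$n_modes > 0L)
      values[seq_len(d$n_modes), i, ] <- d$modes
  }
  structure(list(values = values, seed = config$seed,
                 n_modes = K, n_realizations = I, n_samples = n_samples),
            class = "noise_mode_tensor")
}

#' @export
print.noise_mode_tensor <- function(x, ...) {
  cat("<noise_mode_tensor>", x$n_modes, "x", x$n_realizations, "x",
      x$n_samples, "\n")
  invisible(x)
}

# Streaming alternative to the precomputed tensor: holds only the I x N
# running noise residues and extracts one mode level per call, reproducing
# the precomputed modes bit for bit (the k-th mode depends only on the
# residue after k - 1 extractions).
noise_stream_init <- function(config, n_samples) {
  I <- config$n_realizations
  res <- matrix(0, I, n_samples)
  for (i in seq_len(I))
    res[i, ] <- noise_realization(config$seed, i, n_samples)
  list(residues = res, sift = sift_args(config$sift))
}

noise_stream_next <- function(state) {
  I <- nrow(state$residues)
  n <- ncol(state$residues)
  modes <- matrix(0, I, n)
  a <- state$sift
  for (i in seq_len(I)) {
    r <- state$residues[i, ]
    if (cpp_has_enough_extrema(r)) {
      m <- cpp_sift(r, a$S, a$stop_mode, a$tol, a$fp32)$mode
      modes[i, ] <- m
      state$residues[i, ] <- r - m
    }
  }
  list(modes = modes, state = state)
}

# --- EEMD -----------------------------------------------------------------

#' Ensemble empirical mode decomposition
#'
#' Decomposes `signal + noise_strength * w(i)` independently for each of the
#' I noise realizations and averages mode j across realizations
#' (realizations yielding fewer modes are zero-padded before averaging).
#' The residue is defined as the input minus the sum of the averaged modes,
#' which keeps the decomposition complete. With `noise_strength = 0` every
#' realization is identical and the result reduces to plain [emd()].
#'
#' @param signal A `signal_channel` or numeric vector.
#' @param config An [ensemble_config()].
#' @return An `emd_decomposition`.
#' @export
eemd <- function(signal, config = ensemble_config()) {
  stopifnot(inherits(config, "ensemble_config"))
  x <- as_samples(signal, min_len = 4L)
  n <- length(x)
  eps0 <- config$noise_strength
  a <- sift_args(config$sift)
  if (eps0 == 0)  # all realizations equal the input: the ensemble is EMD
    return(emd(signal, max_modes = config$max_modes, config = config$sift))
  I <- config$n_realizations
  K <- config$max_modes
  decs <- vector("list", I)
  kmax <- 0L
  for (i in seq_len(I)) {
    w <- noise_realization(config$seed, i, n)
    d <- cpp_emd(x + eps0 * w, K, a$S, a$stop_mode, a$tol, a$fp32)
    decs[[i]] <- d
    kmax <- max(kmax, d$n_modes)
  }
  modes <- matrix(0, kmax, n)
  for (i in seq_len(I)) {
    ki <- decs[[i]]$n_modes
    if (ki > 0L)
      modes[seq_len(ki), ] <- modes[seq_len(ki), , drop = FALSE] +
        decs[[i]]$modes
  }
  modes <- modes / I
  residue <- x - if (kmax > 0L) colSums(modes) else 0
  new_decomposition(modes, residue, signal = signal)
}

# --- ICEEMDAN -------------------------------------------------------------

#' Improved CEEMDAN decomposition
#'
#' The improved complete ensemble EMD with adaptive noise. Writing M(.) for
#' the local-mean operator, E_k(.) for the k-th EMD mode of its argument and
#' angle brackets for averaging across realizations, the recursion is
#'
#' \deqn{r_1 = \langle M(x + \beta_0 E_1(w^{(i)})) \rangle,\quad d_1 = x - r_1}
#' \deqn{r_k = \langle M(r_{k-1} + \beta_{k-1} E_k(w^{(i)})) \rangle,\quad
#'       d_k = r_{k-1} - r_k}
#'
#' with \eqn{\beta_k} from [noise_amplitude()] applied to the running
#' residue. Because each mode is the difference of consecutive residues, the
#' modes plus the final residue telescope back to the input exactly
#' (invertibility). Extraction stops after `max_modes` modes or when the
#' residue has fewer than 2 maxima or 2 minima.
#'
#' @param signal A `signal_channel` or numeric vector.
#' @param config An [ensemble_config()].
#' @param keep_residues Store the intermediate residues r_1..r_K in the
#'   result (diagnostics).
#' @return An `iceemdan_result` (also an `emd_decomposition`): `modes`
#'   (n_modes x N matrix), `residue` (final r_K), `betas`, `n_modes`, and
#'   optionally `residues` (n_modes x N).
#' @examples
#' dt <- make_dual_tone()
#' cfg <- ensemble_config(n_realizations = 50, max_modes = 8, seed = 7)
#' dec <- iceemdan(dt$s, cfg)
#' @export
iceemdan <- function(signal, config = ensemble_config(),
                     keep_residues = FALSE) {
  stopifnot(inherits(config, "ensemble_config"))
  x <- as_samples(signal, min_len = 4L)
  n <- length(x)
  I <- config$n_realizations
  K <- config$max_modes
  eps0 <- config$noise_strength
  use_noise <- eps0 > 0
  streaming <- identical(config$noise_tensor, "stream")

  tensor <- NULL
  stream <- NULL
  if (use_noise) {
    if (streaming) stream <- noise_stream_init(config, n)
    else tensor <- precompute_noise_modes(config, n)
  }
  zero_slab <- matrix(0, I, n)

  modes <- matrix(0, K, n)
  residues <- if (keep_residues) matrix(0, K, n) else NULL
  betas <- numeric(K)
  r <- x
  k <- 0L
  while (k < K) {
    if (!cpp_has_enough_extrema(r)) break
    level <- k + 1L
    if (use_noise) {
      if (streaming) {
        nx <- noise_stream_next(stream)
        slab <- nx$modes
        stream <- nx$state
      } else {
        slab <- matrix(tensor$values[level, , ], nrow = I)
      }
    } else slab <- zero_slab
    nm_std <- if (config$beta_rule == "normalized-first-mode")
      mean(apply(slab, 1L, sd_pop)) else NULL
    beta <- noise_amplitude(r, eps0, config$beta_rule, nm_std)
    batch <- make_realizations(r, slab, beta)
    means <- batch_local_mean(batch, config$sift)
    r_new <- ensemble_average(means)
    k <- level
    modes[k, ] <- r - r_new
    betas[k] <- beta
    if (keep_residues) residues[k, ] <- r_new
    r <- r_new
  }

  out <- new_decomposition(modes[seq_len(k), , drop = FALSE], r,
                           signal = signal, class = "iceemdan_result")
  out$betas <- betas[seq_len(k)]
  if (keep_residues) out$residues <- residues[seq_len(k), , drop = FALSE]
  out
}
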