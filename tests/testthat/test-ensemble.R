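test_that("noise-mode precomputation is seeded and reproducible", {
  cfg <- ensemble_config(n_realizations = 8, max_modes = 3, seed = 123,
                         sift = sift_config(5))
  t1 <- precompute_noise_modes(cfg, 256)
  t2 <- precompute_noise_modes(cfg, 256)
  expect_identical(t1$values, t2$values)
  expect_equal(dim(t1$values), c(3, 8, 256))
})

test_that("the first noise mode averages out at the standard-error scale", {
  cfg <- ensemble_config(n_realizations = 200, max_modes = 1, seed = 4,
                         sift = sift_config(10))
  tens <- precompute_noise_modes(cfg, 2000)
  E1 <- tens$values[1, , ]                # 200 x 2000
  per_sample_sd <- mean(apply(E1, 2, sd))
  expect_lt(max(abs(colMeans(E1))), 4 / sqrt(200) * per_sample_sd)
})

test_that("noise modes form a descending-frequency filterbank", {
  cfg <- ensemble_config(n_realizations = 100, max_modes = 4, seed = 9,
                         sift = sift_config(10))
  tens <- precompute_noise_modes(cfg, 2000)
  zc <- function(v) {
    s <- sign(v); s <- s[s != 0]; sum(diff(s) != 0)
  }
  mean_zc <- vapply(1:4, function(k)
    mean(apply(tens$values[k, , ], 1, zc)), numeric(1))
  expect_true(all(diff(mean_zc) < 0))
})

test_that("noise_amplitude follows the residue's population std", {
  expect_identical(noise_amplitude(rep(0, 100), 0.2), 0)
  alt <- rep(c(-1, 1), 50)               # population std exactly 1
  expect_identical(noise_amplitude(alt, 0.2), 0.2)
  set.seed(31)
  r <- rnorm(500)
  sd_oracle <- sqrt(sum((r - sum(r) / 500)^2) / 500)
  expect_equal(noise_amplitude(r, 0.3), 0.3 * sd_oracle, tolerance = 1e-12)
  # normalized rule divides by the noise-mode std
  expect_equal(noise_amplitude(r, 0.3, "normalized-first-mode",
                               noise_mode_std = 2),
               0.3 * sd_oracle / 2, tolerance = 1e-12)
  expect_error(noise_amplitude(r, 0.3, "normalized-first-mode"),
               "noise_mode_std")
  expect_error(noise_amplitude(numeric(0), 0.2), "empty")
})

test_that("make_realizations adds scaled noise rows to the residue", {
  r <- rnorm(64)
  E <- matrix(rnorm(5 * 64), 5, 64)
  b0 <- make_realizations(r, E, 0)
  expect_true(all(apply(b0, 1, identical, r)))
  b1 <- make_realizations(r, E[1, , drop = FALSE], 1)
  expect_bitwise(b1[1, ], r + E[1, ])
  beta <- 0.37
  got <- make_realizations(r, E, beta)
  for (i in 1:5) expect_bitwise(got[i, ], r + beta * E[i, ])
  expect_error(make_realizations(r, E[, 1:10], 1), "matrix")
})

test_that("batch local means equal the per-row sequential loop", {
  cfg <- sift_config(8)
  x <- random_signal(300, seed = 12)
  one <- batch_local_mean(matrix(x, nrow = 1), cfg)
  expect_bitwise(one[1, ], local_mean(x, cfg))

  X <- t(vapply(1:50, function(s) random_signal(200, s), numeric(200)))
  got <- batch_local_mean(X, cfg)
  for (i in 1:50) expect_bitwise(got[i, ], local_mean(X[i, ], cfg))

  Xsame <- matrix(rep(x, 3), nrow = 3, byrow = TRUE)
  gs <- batch_local_mean(Xsame, cfg)
  expect_identical(gs[1, ], gs[2, ])
  expect_identical(gs[2, ], gs[3, ])
})

test_that("ensemble_average is the columnwise mean", {
  v <- rnorm(32)
  expect_bitwise(ensemble_average(matrix(v, 1)), v)
  expect_identical(ensemble_average(rbind(v, -v)), rep(0, 32))
  M <- matrix(rnorm(200), 10, 20)
  expect_equal(ensemble_average(M), apply(M, 2, mean), tolerance = 1e-15)
})

test_that("eemd reduces to emd without noise and recovers the dual tones", {
  dt <- make_dual_tone()
  cfg0 <- ensemble_config(n_realizations = 1, max_modes = 8,
                          noise_strength = 0, seed = 5)
  expect_identical(eemd(dt$s, cfg0)$modes,
                   emd(dt$s, max_modes = 8)$modes)

  cfg <- ensemble_config(n_realizations = 200, max_modes = 10, seed = 5)
  d <- eemd(dt$s, cfg)
  rep <- match_modes(d, list(dt$s1, dt$s2))
  expect_gte(rep$pairs$similarity[1], 0.95)
  expect_gte(rep$pairs$similarity[2], 0.95)
  expect_lt(reconstruction_error(dt$s, d), 1e-9)
})

test_that("averaged eemd modes obey the sqrt(I) noise-cancellation law", {
  x <- sin(2 * pi * 0.1 * (0:499))
  mode1 <- function(I, seed) {
    cfg <- ensemble_config(n_realizations = I, max_modes = 4, seed = seed,
                           sift = sift_config(10), noise_strength = 0.2)
    eemd(x, cfg)$modes[1, ]
  }
  seeds <- 101:112
  m100 <- t(vapply(seeds, function(s) mode1(100, s), numeric(500)))
  m400 <- t(vapply(seeds, function(s) mode1(400, s), numeric(500)))
  ratio <- mean(apply(m100, 2, sd)) / mean(apply(m400, 2, sd))
  expect_gt(ratio, 1.6)
  expect_lt(ratio, 2.4)
})

test_that("iceemdan is complete and its modes telescope the residues", {
  dt <- make_dual_tone()
  cfg <- ensemble_config(n_realizations = 30, max_modes = 8, seed = 2)
  d <- iceemdan(dt$s, cfg, keep_residues = TRUE)
  expect_lt(reconstruction_error(dt$s, d), 1e-9)
  expect_length(d$betas, d$n_modes)
  r_prev <- as.numeric(dt$s)
  for (k in seq_len(d$n_modes)) {
    expect_bitwise(d$modes[k, ], r_prev - d$residues[k, ])
    r_prev <- d$residues[k, ]
  }
  expect_bitwise(d$residue, r_prev)

  for (seed in 1:5) {
    x <- random_signal(256, seed)
    di <- iceemdan(x, ensemble_config(10, 6, seed = seed))
    expect_lt(reconstruction_error(x, di), 1e-9)
  }
})

test_that("zero-noise iceemdan equals the sequential iterated-local-mean", {
  x <- random_signal(512, seed = 44)
  cfg <- ensemble_config(n_realizations = 7, max_modes = 6,
                         noise_strength = 0, seed = 1)
  got <- iceemdan(x, cfg)
  want <- oracle_iterated_local_mean(x, 6, cfg$sift)
  expect_identical(got$modes, unname(want$modes))
  expect_identical(got$residue, want$residue)
})

test_that("streaming noise extraction matches the precomputed tensor", {
  dt <- make_dual_tone()
  base <- ensemble_config(n_realizations = 25, max_modes = 6, seed = 13)
  stream <- ensemble_config(n_realizations = 25, max_modes = 6, seed = 13,
                            noise_tensor = "stream")
  d1 <- iceemdan(dt$s, base)
  d2 <- iceemdan(dt$s, stream)
  expect_identical(d1$modes, d2$modes)
  expect_identical(d1$residue, d2$residue)
})

test_that("identical configuration and seed give bitwise-identical runs", {
  dt <- make_dual_tone()
  cfg <- ensemble_config(n_realizations = 40, max_modes = 8, seed = 99)
  d1 <- iceemdan(dt$s, cfg)
  d2 <- iceemdan(dt$s, cfg)
  expect_identical(d1$modes, d2$modes)
  expect_identical(d1$residue, d2$residue)
  expect_identical(d1$betas, d2$betas)
})

test_that("iceemdan mode center frequencies decrease with mode index", {
  dt <- make_dual_tone()
  d <- iceemdan(dt$s, ensemble_config(n_realizations = 100, max_modes = 10,
                                      seed = 3))
  zc <- function(v) {
    s <- sign(v); s <- s[s != 0]; sum(diff(s) != 0)
  }
  counts <- apply(d$modes, 1, zc)
  expect_true(all(diff(counts) < 0))
})
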