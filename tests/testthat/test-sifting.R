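test_that("a pure tone is already an IMF and sifting preserves it", {
  x <- sin(2 * pi * 0.05 * (0:999))
  m <- sift(x, sift_config(10))
  expect_false(attr(m, "monotonic"))
  expect_gte(similarity_index(m, x), 0.99)
})

test_that("signals without enough extrema come back flagged monotonic", {
  ramp <- seq(0, 1, length.out = 100)
  m <- sift(ramp)
  expect_true(attr(m, "monotonic"))
  expect_identical(as.numeric(m), ramp)
})

test_that("one sifting pass is exactly envelope-mean subtraction", {
  x <- random_signal(256, seed = 3)
  m <- sift(x, sift_config(1))
  direct <- x - mean_envelope(build_envelope_pair(x))
  expect_bitwise(m, direct)
})

test_that("sift and local_mean partition the signal exactly", {
  for (seed in c(2, 9, 17)) {
    x <- random_signal(400, seed)
    # definitional identity, bitwise: M(x) is x minus the sifted mode
    expect_bitwise(local_mean(x), x - as.numeric(sift(x)))
    # summed reconstruction agrees to the last ulp
    expect_equal(as.numeric(sift(x)) + local_mean(x), x,
                 tolerance = 1e-15)
  }
})

test_that("local_mean is near zero for a tone and tracks an added trend", {
  n <- 0:999
  tone <- sin(2 * pi * 0.05 * n)
  interior <- 21:979
  lm0 <- local_mean(tone)
  expect_lt(max(abs(lm0[interior])), 0.05)
  trend <- 0.01 * n
  lm1 <- local_mean(tone + trend)
  expect_lt(max(abs(lm1[interior] - trend[interior])), 0.1)
})

test_that("emd separates well-spaced tones and returns nothing for a ramp", {
  ramp <- seq(-1, 1, length.out = 64)
  d <- emd(ramp)
  expect_equal(d$n_modes, 0L)
  expect_identical(d$residue, ramp)

  n <- 0:1999
  fast <- sin(2 * pi * 0.2 * n)
  slow <- sin(2 * pi * 0.02 * n)
  d <- emd(fast + slow, max_modes = 8, config = sift_config(10))
  expect_gte(d$n_modes, 2L)
  interior <- 101:1900
  expect_gte(similarity_index(d$modes[1, interior], fast[interior]), 0.99)
  expect_gte(similarity_index(d$modes[2, interior], slow[interior]), 0.98)
})

test_that("emd is complete for random signals", {
  worst <- 0
  for (seed in 1:100) {
    x <- random_signal(256, seed)
    d <- emd(x, max_modes = 8)
    worst <- max(worst, max(abs(reconstruct(d) - x)) / max(abs(x)))
  }
  expect_lt(worst, 1e-9)
})

test_that("a single tone yields one oscillatory mode and a tiny residue", {
  x <- sin(2 * pi * 0.05 * (0:999))
  d <- emd(x, max_modes = 6)
  interior <- 21:979
  expect_lte(sum(d$residue[interior]^2) +
               if (d$n_modes > 1)
                 sum(colSums(d$modes[-1, interior, drop = FALSE])^2) else 0,
             0.01 * sum(x[interior]^2))
  expect_gte(similarity_index(d$modes[1, ], x), 0.99)
})

test_that("sifting an extracted mode again barely changes it", {
  x <- random_signal(600, seed = 21)
  m <- as.numeric(sift(x, sift_config(10)))
  m2 <- as.numeric(sift(m, sift_config(1)))
  expect_lt(sqrt(sum((m2 - m)^2) / sum(m^2)), 0.05)
})

test_that("the threshold stop mode terminates early when converged", {
  x <- sin(2 * pi * 0.05 * (0:499))  # nearly an IMF from the start
  m <- sift(x, sift_config(50, "threshold", threshold = 1e-4))
  expect_lt(attr(m, "iterations"), 50L)
  expect_gte(similarity_index(m, x), 0.99)
})

test_that("single-precision mode quantizes the pipeline to float32", {
  float32_roundtrip <- function(v) {
    con <- rawConnection(raw(0), "wb")
    writeBin(v, con, size = 4L)
    out <- readBin(rawConnectionValue(con), "double", n = length(v),
                   size = 4L)
    close(con)
    out
  }
  x <- random_signal(256, seed = 8)
  m <- as.numeric(sift(x, sift_config(5, precision = "single")))
  # every output sample is exactly representable as a 32-bit float
  expect_identical(m, float32_roundtrip(m))
  # and differs from the double-precision pipeline only at float32 scale
  md <- as.numeric(sift(x, sift_config(5)))
  expect_false(identical(m, md))
  expect_lt(max(abs(m - md)), 1e-4)
})
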