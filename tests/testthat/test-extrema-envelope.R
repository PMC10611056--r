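test_that("find_extrema locates interior extrema with the plateau rule", {
  ex <- find_extrema(c(0, 1, 0))
  expect_equal(ex$max_positions, 1L)
  expect_equal(ex$max_values, 1)
  expect_length(ex$min_positions, 0)

  # plateaus count once, at the first index of the run
  ex <- find_extrema(c(0, 1, 1, 0))
  expect_equal(ex$max_positions, 1L)
  ex <- find_extrema(c(0, -1, -1, -1, 0, 2))
  expect_equal(ex$min_positions, 1L)
  expect_length(ex$max_positions, 0)

  # plateaus touching a boundary are not interior extrema
  ex <- find_extrema(c(1, 1, 0, 1, 1))
  expect_equal(ex$min_positions, 2L)
  expect_length(ex$max_positions, 0)

  # constant signal: empty sets, not an error
  ex <- find_extrema(rep(2, 10))
  expect_length(ex$max_positions, 0)
  expect_length(ex$min_positions, 0)

  expect_error(find_extrema(c(0, NA, 1)), "non-finite")
})

test_that("find_extrema matches the brute-force neighbour-scan oracle", {
  for (seed in 1:1000) {
    set.seed(seed)
    x <- rnorm(64)
    got <- find_extrema(x)
    want <- oracle_extrema(x)
    expect_identical(got$max_positions, want$max_positions)
    expect_identical(got$min_positions, want$min_positions)
  }
})

test_that("the slow dual-tone component has 65 interior maxima", {
  dt <- make_dual_tone()
  got <- find_extrema(dt$s2)
  want <- oracle_extrema(dt$s2)
  expect_identical(got$max_positions, want$max_positions)
  expect_length(got$max_positions, 65L)
})

test_that("tridiagonal solver agrees with a dense solve", {
  # identity system
  expect_equal(solve_tridiagonal(rep(0, 4), rep(1, 5), rep(0, 4), 1:5),
               as.numeric(1:5))
  # 1x1 system
  expect_equal(solve_tridiagonal(numeric(0), 4, numeric(0), 6), 1.5)

  set.seed(11)
  for (n in c(2, 3, 8, 33, 128, 512)) {
    sub <- runif(n - 1, -1, 1)
    super <- runif(n - 1, -1, 1)
    diag <- 2 + abs(c(0, sub)) + abs(c(super, 0)) + runif(n)
    rhs <- rnorm(n)
    got <- solve_tridiagonal(sub, diag, super, rhs)
    expect_lt(max(abs(got - oracle_tridiag_solve(sub, diag, super, rhs))),
              1e-10)
  }

  expect_error(solve_tridiagonal(c(1), c(0, 1), c(1), c(1, 1)), "row 1")
})

test_that("natural spline interpolates, is C2, and degenerates to a line", {
  # 2 knots -> linear segment
  co <- natural_spline_coefficients(c(0, 10), c(1, 3))
  expect_equal(unname(co$coefficients[1, ]), c(1, 0.2, 0, 0))

  # knots on a straight line reproduce the line exactly
  t <- c(0, 3, 7, 12, 20)
  co <- natural_spline_coefficients(t, 2 * t + 1)
  q <- seq(-2, 25, by = 0.5)
  expect_equal(evaluate_spline(co, q), 2 * q + 1, tolerance = 1e-12)

  # knots at maxima of a tone: exact interpolation and C2 continuity
  n <- 0:199
  x <- sin(2 * pi * 0.05 * n)
  mx <- find_extrema(x)$max_positions
  co <- natural_spline_coefficients(mx, x[mx + 1])
  expect_lt(max(abs(evaluate_spline(co, mx) - x[mx + 1])), 1e-12)
  cf <- co$coefficients
  h <- diff(mx)
  for (i in seq_len(nrow(cf) - 1)) {
    left <- 2 * cf[i, 3] + 6 * cf[i, 4] * h[i]   # S_i''(t_{i+1})
    right <- 2 * cf[i + 1, 3]                     # S_{i+1}''(t_{i+1})
    expect_lt(abs(left - right), 1e-9)
  }
  # natural boundary: zero second derivative at the end knots
  expect_lt(abs(2 * cf[1, 3]), 1e-12)
  m <- nrow(cf)
  expect_lt(abs(2 * cf[m, 3] + 6 * cf[m, 4] * h[m]), 1e-9)

  expect_error(natural_spline_coefficients(1, 2), "degenerate")
  expect_error(natural_spline_coefficients(c(1, 1), c(2, 3)),
               "strictly increasing")
})

test_that("evaluate_spline matches a direct Horner oracle and handles ends", {
  set.seed(5)
  t <- sort(sample(0:60, 5))
  co <- natural_spline_coefficients(t, rnorm(5))
  q <- 0:60
  expect_lt(max(abs(evaluate_spline(co, q) -
                    oracle_eval_spline(co$knots, co$coefficients, q))),
            1e-12)
  # knot positions reproduce knot values exactly
  expect_identical(evaluate_spline(co, t[1]), unname(co$coefficients[1, 1]))
  # nearest policy clamps beyond the span
  lo <- evaluate_spline(co, t[1] - 10, "nearest")
  expect_equal(lo, evaluate_spline(co, t[1]))
})

test_that("envelopes hug a constant-amplitude tone and track trends", {
  n <- 0:999
  x <- sin(2 * pi * 0.05 * n)
  env <- build_envelope_pair(x)
  interior <- 21:979  # exclude one period at each end
  expect_lt(max(abs(env$upper[interior] - 1)), 0.01)
  expect_lt(max(abs(env$lower[interior] + 1)), 0.01)
  expect_true(all(is.finite(env$upper)) && all(is.finite(env$lower)))

  # minimal valid input: exactly 2 maxima and 2 minima
  y <- c(0, 1, 0, -1, 0, 1, 0, -1, 0)
  ey <- find_extrema(y)
  expect_length(ey$max_positions, 2L)
  expect_length(ey$min_positions, 2L)
  env2 <- build_envelope_pair(y, ey)
  expect_true(all(is.finite(env2$upper)) && all(is.finite(env2$lower)))
  expect_length(env2$upper, length(y))

  # mirrored extension keeps the envelope mean on a linear trend
  trend <- 0.01 * n
  env3 <- build_envelope_pair(trend + x)
  mid <- mean_envelope(env3)
  expect_lt(max(abs(mid[interior] - trend[interior])), 0.05)

  expect_error(build_envelope_pair(seq_len(50)), class = "iceemdan_monotonic")
})

test_that("mean_envelope is the elementwise midline", {
  v <- rnorm(100)
  expect_identical(mean_envelope(list(upper = v, lower = v)), v)
  expect_identical(mean_envelope(list(upper = rep(1, 5), lower = rep(-1, 5))),
                   rep(0, 5))
  u <- rnorm(64); l <- rnorm(64)
  expect_identical(mean_envelope(list(upper = u, lower = l)), (u + l) / 2)
  expect_error(mean_envelope(list(upper = 1:3, lower = 1:4)), "length")
})
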