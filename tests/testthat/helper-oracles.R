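# Independent oracles used across the suite. These are deliberately naive
# implementations (per-sample scans, dense solves, direct arithmetic) kept
# separate from the package's code paths.

# brute-force per-sample neighbour scan (strict comparisons; suitable for
# continuous-valued signals where ties have probability zero)
oracle_extrema <- function(x) {
  n <- length(x)
  mx <- integer(0)
  mn <- integer(0)
  for (i in 2:(n - 1)) {
    if (x[i] > x[i - 1] && x[i] > x[i + 1]) mx <- c(mx, i - 1L)
    if (x[i] < x[i - 1] && x[i] < x[i + 1]) mn <- c(mn, i - 1L)
  }
  list(max_positions = mx, min_positions = mn)
}

# dense materialization of a tridiagonal system solved with base::solve
oracle_tridiag_solve <- function(sub, diag, super, rhs) {
  n <- length(diag)
  A <- matrix(0, n, n)
  diag(A) <- diag
  if (n > 1) {
    A[cbind(2:n, 1:(n - 1))] <- sub
    A[cbind(1:(n - 1), 2:n)] <- super
  }
  as.numeric(solve(A, rhs))
}

# direct Horner evaluation of stored segment coefficients
oracle_eval_spline <- function(knots, coef, q) {
  m <- length(knots)
  vapply(q, function(u) {
    seg <- if (u <= knots[1]) 1L
           else if (u >= knots[m]) m - 1L
           else findInterval(u, knots, rightmost.closed = TRUE)
    dx <- u - knots[seg]
    coef[seg, 1] + dx * (coef[seg, 2] + dx * (coef[seg, 3] + dx * coef[seg, 4]))
  }, numeric(1))
}

# two-pass moment-based covariance/variance
oracle_similarity <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n
  my <- sum(y) / n
  cxy <- sum((x - mx) * (y - my)) / (n - 1)
  vx <- sum((x - mx)^2) / (n - 1)
  vy <- sum((y - my)^2) / (n - 1)
  abs(cxy) / sqrt(vx * vy)
}

# sequential iterated-local-mean recursion (the zero-noise ICEEMDAN limit)
oracle_iterated_local_mean <- function(x, max_modes, config) {
  r <- as.numeric(x)
  modes <- list()
  for (k in seq_len(max_modes)) {
    ex <- find_extrema(r)
    if (length(ex$max_positions) < 2 || length(ex$min_positions) < 2) break
    r_new <- local_mean(r, config)
    modes[[k]] <- r - r_new
    r <- r_new
  }
  list(modes = do.call(rbind, modes), residue = r)
}

# a random piecewise-smooth test signal: sum of tones with random phases
# plus a polynomial trend
random_signal <- function(n, seed) {
  set.seed(seed)
  t <- seq(0, 1, length.out = n)
  x <- numeric(n)
  for (f in sample(3:40, 3)) x <- x + runif(1, 0.3, 1) * sin(2 * pi * f * t + runif(1, 0, 2 * pi))
  x + runif(1, -1, 1) * t + 0.3 * rnorm(n)
}

expect_bitwise <- function(a, b) expect_true(identical(as.numeric(a), as.numeric(b)))
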