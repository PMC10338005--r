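# Independent oracles and small utilities shared across the test files.
# Everything here is deliberately written with generic tools (dense solves,
# time quadrature, spectral differentiation), not with the package's own
# discretisations, so that the tests compare two genuinely different routes.

# Least-squares slope of log(err) vs log(h): measured convergence order.
convergence_order <- function(h, err) {
  keep <- err > 0
  stats::coef(stats::lm(log(err[keep]) ~ log(h[keep])))[[2L]]
}

# Generic two-point boundary-value solve of (1/alpha^2) u'' = rhs(y) on
# [0, H] with u(0) = u(H) = 0, by a second-order central-difference
# tridiagonal system on a fine uniform grid. Used as the independent route
# to the steady-streaming and buoyancy velocity profiles.
bvp_profile <- function(rhs_fun, H, alpha, N = 4001L) {
  y <- seq(0, H, length.out = N)
  h <- y[2L] - y[1L]
  rhs <- rep_len(alpha^2 * rhs_fun(y[2:(N - 1L)]), N - 2L)
  # tridiagonal (1, -2, 1)/h^2 u = rhs
  a <- rep(1, N - 3L); b <- rep(-2, N - 2L); d <- rhs * h^2
  # Thomas algorithm
  for (i in 2:(N - 2L)) {
    w <- a[i - 1L] / b[i - 1L]
    b[i] <- b[i] - w * a[i - 1L]
    d[i] <- d[i] - w * d[i - 1L]
  }
  u <- numeric(N - 2L)
  u[N - 2L] <- d[N - 2L] / b[N - 2L]
  for (i in (N - 3L):1L) u[i] <- (d[i] - a[i] * u[i + 1L]) / b[i]
  list(y = y, u = c(0, u, 0))
}

# Period average over the fast time of a product expression, by trapezoid
# over nt equally spaced samples of one oscillation (exact for the
# quadratic-in-harmonics integrands arising here once nt > 4).
time_average <- function(fun, nt = 32L) {
  ts <- 2 * pi * (seq_len(nt) - 1L) / nt
  acc <- NULL
  for (t in ts) {
    v <- fun(t)
    acc <- if (is.null(acc)) v / nt else acc + v / nt
  }
  acc
}

# Spectral (FFT) derivative of a periodic sample set on [0, L) -- exact for
# band-limited data; used as the clean spatial oracle for the RK3 time-order
# test.
spectral_deriv <- function(v, L) {
  n <- length(v)
  k <- c(0:(n %/% 2L), (-(n - n %/% 2L - 1L)):(-1L)) * (2 * pi / L)
  if (n %% 2L == 0L) k[n %/% 2L + 1L] <- 0
  Re(stats::fft(1i * k * stats::fft(v), inverse = TRUE)) / n
}

# Linear interpolation of a mapped-grid column field onto arbitrary y.
interp_column <- function(eta, values, y, H) {
  stats::approx(eta * H, values, xout = y, rule = 2L)$y
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(abs(actual / expected - 1), tol)
}
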