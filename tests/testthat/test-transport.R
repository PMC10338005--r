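# Transport solver: initial condition, spatial operators, time stepping,
# conservation, and the small-sigma limit.

test_that("the truncated-Gaussian bolus has a saturated core with the analytic edge", {
  p <- channel_params(n = 3)
  g <- channel_grid(p, 200, 9)
  c0 <- initial_bolus(g, x0 = 1.75, delta = 0.2)
  expect_equal(max(abs(c0 - matrix(c0[1L, ], g$neta, g$nx, byrow = TRUE))), 0)
  ix0 <- which.min(abs(g$x - 1.75))
  expect_equal(c0[1L, ix0], 1)
  # plateau extends to |x - x0| = delta sqrt(log(3/2)) / 4, Gaussian beyond
  edge <- 0.2 * sqrt(log(1.5)) / 4
  inside <- abs(g$x - 1.75) < edge - g$dx
  outside <- abs(g$x - 1.75) > edge + g$dx
  expect_true(all(c0[1L, inside] == 1))
  expect_true(all(c0[1L, outside] < 1))
  expect_lt(max(c0[1L, abs(g$x - 1.75) > 5 * 0.2]), 1e-10)
  expect_warning(initial_bolus(g, x0 = 0.2, delta = 0.5), "touches")
  expect_error(initial_bolus(g, x0 = 4, delta = 0.2), "inside")
  expect_error(initial_bolus(g, x0 = 1, delta = 0), "positive")
})

test_that("upwind advection is exact on affine data and second order on smooth data", {
  p <- channel_params(alpha = 4, beta = 0, n = 1)
  g <- channel_grid(p, 64, 17)
  cx <- matrix(g$x, g$neta, g$nx, byrow = TRUE)
  ones <- matrix(1, g$neta, g$nx)
  term <- advection_term(cx, ones, 0 * ones, g)
  expect_equal(max(abs(term[, 3:(g$nx - 2L)] - 1)), 0, tolerance = 1e-12)
  expect_equal(max(abs(advection_term(0 * cx + 2.5, ones, ones, g))), 0,
               tolerance = 1e-12)

  # manufactured smooth field with sign-changing velocities
  err_at <- function(nx) {
    gg <- channel_grid(p, nx, 2L * nx + 1L)
    X <- matrix(gg$x, gg$neta, gg$nx, byrow = TRUE)
    E <- matrix(gg$eta, gg$neta, gg$nx)
    cc <- sin(2 * pi * X) * (1 + 0.5 * cos(pi * E))
    u <- 0.7 + 0.5 * sin(2 * pi * X) # changes sign
    w <- 0.3 * E * (1 - E) * cos(2 * pi * X)
    exact <- u * (2 * pi * cos(2 * pi * X)) * (1 + 0.5 * cos(pi * E)) +
      w * sin(2 * pi * X) * (-0.5 * pi * sin(pi * E))
    approx_ <- advection_term(cc, u, w, gg)
    inner <- 3:(gg$nx - 2L)
    max(abs((approx_ - exact)[3:(gg$neta - 2L), inner]))
  }
  ns <- c(32L, 64L, 128L)
  errs <- vapply(ns, err_at, numeric(1L))
  order <- convergence_order(1 / ns, errs)
  expect_gt(order, 1.8)
  expect_lt(order, 2.4)
})

test_that("compact diffusion is exact on quadratics and fourth order on cos(pi eta)", {
  p <- channel_params(alpha = 2, sigma = 0.5, beta = 0, n = 1)
  g <- channel_grid(p, 16, 33)
  E <- matrix(g$eta, g$neta, g$nx)
  coef <- 1 / (p$alpha^2 * p$sigma) # H = 1
  quad <- 3 + 0 * E^2 # eta-independent field: term must vanish
  expect_lt(max(abs(diffusion_term(quad, p, g))), 1e-11)

  err_at <- function(ne) {
    gg <- channel_grid(p, 16, ne)
    EE <- matrix(gg$eta, gg$neta, gg$nx)
    cc <- cos(pi * EE) # satisfies the Neumann walls
    exact <- -coef * pi^2 * cos(pi * EE)
    max(abs(diffusion_term(cc, p, gg) - exact))
  }
  ns <- c(17L, 33L, 65L, 129L)
  errs <- vapply(ns, err_at, numeric(1L))
  order <- convergence_order(1 / (ns - 1L), errs)
  expect_gt(order, 3.7)
  expect_lt(order, 4.3)
})

test_that("compact diffusion preserves the transverse solute integral on no-flux profiles", {
  p <- channel_params(alpha = 1, sigma = 1, beta = 0, n = 1)
  g <- channel_grid(p, 16, 41)
  solver <- wavechannel:::compact_eta_solver(g$neta, g$deta)
  E <- matrix(g$eta, g$neta, g$nx)
  # superposition of Neumann-compatible modes: the integral of d2c/deta2
  # is the wall-gradient difference, i.e. exactly zero for these profiles
  cc <- 0.4 + 0.3 * cos(pi * E) + 0.2 * cos(2 * pi * E) + 0.1 * cos(3 * pi * E)
  d2 <- wavechannel:::compact_d2_eta(cc, solver)
  expect_lt(max(abs(trapz_uniform(d2, g$deta))), 1e-8)
  # and the operator annihilates transversely uniform fields exactly
  d2c <- wavechannel:::compact_d2_eta(matrix(2.5, g$neta, g$nx), solver)
  expect_equal(max(abs(d2c)), 0)
})

test_that("TVD Runge-Kutta stepping is third-order accurate in time", {
  # pure advection of a periodic profile with an exact (spectral) space
  # derivative isolates the temporal error; the oracle is the exact
  # translation by the method of characteristics
  L <- 1; u0 <- 0.9
  nxs <- 32L # keeps u k_max dt inside the RK3 stability interval at every dt
  x <- seq(0, L, length.out = nxs + 1L)[-(nxs + 1L)]
  c0 <- exp(sin(2 * pi * x))
  rhs <- function(cm) -u0 * matrix(spectral_deriv(as.vector(cm), L), ncol = 1L)
  T_end <- 0.5
  errs <- vapply(c(40L, 80L, 160L), function(nsteps) {
    dt <- T_end / nsteps
    cm <- matrix(c0, ncol = 1L)
    for (k in seq_len(nsteps)) cm <- wavechannel:::rk3_update(cm, dt, rhs)
    exact <- exp(sin(2 * pi * ((x - u0 * T_end) %% L)))
    max(abs(as.vector(cm) - exact))
  }, numeric(1L))
  order <- convergence_order(T_end / c(40L, 80L, 160L), errs)
  expect_gt(order, 2.7)
  expect_lt(order, 3.3)
})

test_that("uniform concentration without buoyancy is an exact steady state", {
  p <- channel_params(alpha = 4, beta = 0.3, Ri = 0, sigma = 1, n = 1)
  g <- channel_grid(p, 32, 17)
  c_init <- matrix(0.42, g$neta, g$nx)
  run <- run_transport(p, 32, 17, c_init = c_init, tau_end = 0.2,
                       snap_dt = 0.1, keep_fields = FALSE)
  expect_lt(max(abs(run$c_final - 0.42)), 1e-12)
})

test_that("flat channel without drift relaxes to the transverse mean by pure diffusion", {
  p <- channel_params(alpha = 2, beta = 0, Ri = 0, sigma = 1, n = 1)
  g <- channel_grid(p, 32, 33)
  c_init <- outer(0.5 + 0.3 * cos(pi * g$eta), rep(1, g$nx))
  run <- run_transport(p, 32, 33, c_init = c_init, tau_end = 2,
                       snap_dt = 1, keep_fields = FALSE)
  # decay rate of the cos(pi eta) mode is pi^2/(alpha^2 sigma)
  dev <- max(abs(run$c_final - 0.5))
  expect_lt(dev, 0.3 * exp(-pi^2 / 4 * 2) * 1.1)
  expect_gt(dev, 0.3 * exp(-pi^2 / 4 * 2) * 0.5)
  d <- run$diagnostics
  expect_lt(abs(d$M[nrow(d)] / d$M[1L] - 1), 1e-12) # diffusion conserves mass
})

test_that("mass is conserved and the section-flux identity closes under refinement", {
  p <- channel_params(alpha = 4, beta = 0.2, Ri = 1, sigma = 1, n = 3)
  run <- run_transport(p, 48, 25, tau_end = 1, snap_dt = 0.5,
                       keep_fields = FALSE)
  d <- run$diagnostics
  expect_lt(abs(d$M[nrow(d)] / d$M[1L] - 1), 5e-3)
  expect_lt(max(abs(d$phi_end_0), abs(d$phi_end_n)), 1e-8)

  # discrete flux identity: H <rhs> integrated over eta must match -dphi/dx
  # up to truncation, contracting under refinement
  resid_at <- function(nx, ne) {
    g <- channel_grid(p, nx, ne)
    md <- mean_drift(p, nx, ne)
    cc <- initial_bolus(g, 1.75, 0.2) *
      outer(1 + 0.2 * cos(pi * g$eta), rep(1, g$nx))
    bl <- buoyancy_flow(cc, p, g)
    u <- wavechannel:::tile_cell_field(md$u_ss + md$u_sd, p$n) + bl$u_b
    v <- wavechannel:::tile_cell_field(md$v_ss + md$v_sd, p$n) + bl$v_b
    w <- (v - u * outer(g$eta, g$Hx)) / matrix(g$H, g$neta, g$nx, byrow = TRUE)
    w[c(1L, g$neta), ] <- 0
    rhs <- -advection_term(cc, u, w, g) + diffusion_term(cc, p, g)
    Cdot <- g$H * trapz_uniform(rhs, g$deta)
    phi <- g$H * trapz_uniform(u * cc, g$deta)
    dphidx <- wavechannel:::deriv_x_onesided(matrix(phi, nrow = 1L), g$dx)
    inner <- 5:(g$nx - 4L)
    max(abs(Cdot + as.vector(dphidx))[inner])
  }
  r1 <- resid_at(32L, 17L)
  r2 <- resid_at(64L, 33L)
  expect_lt(r2, r1)
})

test_that("low-sigma solver freezes without buoyancy and conserves the gap-weighted mass", {
  p0 <- channel_params(alpha = 4, beta = 0.2, Ri = 0, n = 3)
  ls0 <- low_sigma_transport(p0, 64, tau_end = 1, snap_dt = 0.5)
  prof0 <- ls0$profiles[ls0$profiles$tau == 0, ]
  prof1 <- ls0$profiles[ls0$profiles$tau == 1, ]
  expect_equal(prof1$c, prof0$c, tolerance = 1e-14)

  p <- channel_params(alpha = 4, beta = 0.2, Ri = 1, n = 3)
  ls <- low_sigma_transport(p, 96, tau_end = 1, snap_dt = 0.5)
  d <- ls$diagnostics
  expect_lt(abs(d$M[nrow(d)] / d$M[1L] - 1), 1e-6)
  expect_true(all(d$Q_b < 0))
})

test_that("low-sigma transport translates a superposed bump at the chimney speed", {
  # flat channel: Q_B depends only on the conserved total solute, so the
  # coefficient is frozen and any profile translates rigidly at Q_B / H
  p <- channel_params(alpha = 4, beta = 0, Ri = 1, n = 3)
  nx_cell <- 128L
  x <- seq(0, 3, length.out = 3L * nx_cell + 1L)
  background <- 0.3
  bump <- 0.2 * exp(-((x - 1.8) / 0.12)^2)
  ls <- low_sigma_transport(p, nx_cell, c_init = background + bump,
                            tau_end = 0.3, snap_dt = 0.3)
  qb <- ls$diagnostics$Q_b[1L]
  expect_rel_equal(qb, -p$alpha^2 * p$Ri * trapz_uniform(background + bump,
                                                         x[2L]) / (12 * 3),
                   1e-6)
  com <- function(cv) {
    dev <- cv - background
    trapz_uniform(x * dev, x[2L]) / trapz_uniform(dev, x[2L])
  }
  shift <- com(ls$c_final) - com(background + bump)
  expect_rel_equal(shift, qb * 0.3, 0.05)
  expect_lt(shift, 0) # upward
})
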