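# Concentration-dependent buoyancy-induced mean flow on the full channel.
#
# A solute of density different from the carrier fluid drives a slow mean
# flow through the longitudinal pressure gradient it induces. The solve has
# the same quadrature structure as the steady streaming with the Reynolds
# forcing replaced by Ri * c, but the closure is non-local: because c is not
# spatially periodic, the pressure gradient couples all n cells, and the net
# "chimney" flow rate Q_B is generally nonzero. With x measured downward from
# the upper end, a light solute (Ri > 0) produces an upward draft, Q_B < 0.
# The solve is quasi-steady: a pure function of the instantaneous c.

#' First transverse moment of the concentration
#'
#' `m(x) = integral_0^H c y (H - y) dy = H^3 integral_0^1 c eta (1 - eta) deta`,
#' the weighting through which the solute column drives the buoyancy pressure
#' gradient.
#'
#' @param c_field Real `[neta, nx]` concentration matrix on the mapped grid.
#' @param grid The full-channel [channel_grid()].
#' @return Numeric profile `m(x)` of length `nx`.
#' @export
buoyancy_moment <- function(c_field, grid) {
  stopifnot(is.matrix(c_field), nrow(c_field) == grid$neta,
            ncol(c_field) == grid$nx)
  grid$H^3 * trapz_uniform(c_field * (grid$eta * (1 - grid$eta)), grid$deta)
}

#' Buoyancy-induced pressure gradient (per unit Richardson number)
#'
#' `(1/Ri) dpB/dx = (6/H^3) [ (integral_0^n H^-3 m dx) / (n integral_0^1 H^-3 dx) - m ]`,
#' the closure that makes the buoyancy pressure vanish at both open ends.
#'
#' @param m Moment profile from [buoyancy_moment()].
#' @param grid Full-channel [channel_grid()].
#' @return Numeric profile of length `nx`; its integral over `[0, n]`
#'   vanishes by construction.
#' @export
buoyancy_pressure_gradient <- function(m, grid) {
  Hm3 <- grid$H^-3
  num <- trapz_uniform(Hm3 * m, grid$dx)
  x1 <- seq(0, 1, length.out = grid$nx_cell + 1L)
  I3 <- trapz_uniform(channel_width(x1, grid$beta)^-3, 1 / grid$nx_cell)
  (6 * Hm3) * (num / (grid$n * I3) - m)
}

#' Buoyancy-induced mean velocity field
#'
#' Integrates the time-averaged momentum balance forced by `Ri * c` with
#' no-slip walls and equal end pressures. Returns the velocity components,
#' the pressure-gradient profile and the net flow rate, computed two ways as
#' a consistency check: by direct quadrature of `uB`, and from the closed
#' form `Q_B = -alpha^2 Ri [integral_0^n H^-3 m dx] / (2 n integral_0^1 H^-3 dx)`.
#' All outputs are exactly linear in `Ri * c`.
#'
#' @param c_field Real `[neta, nx]` concentration on the full-channel grid.
#' @param params A [channel_params()] object.
#' @param grid Full-channel [channel_grid()].
#' @param check Logical; run the two-way flow-rate consistency assertion.
#' @param tol Tolerance of the assertion, relative to
#'   `alpha^2 |Ri| max(m)`; the discrete closure makes the two routes agree
#'   to round-off, so the default is near machine precision.
#' @return Object of class `"buoyancy_flow"`: matrices `u_b`, `v_b`, profiles
#'   `m`, `dpb_dx`, streamfunction `psi_b`, and scalars `Q_b` (quadrature)
#'   and `Q_b_closed`.
#' @examples
#' p <- channel_params(alpha = 4, beta = 0, Ri = 1, n = 1)
#' g <- channel_grid(p, 32, 33)
#' bf <- buoyancy_flow(matrix(1, 33, g$nx), p, g)
#' bf$Q_b # -alpha^2 Ri / 12 = -4/3
#' @export
buoyancy_flow <- function(c_field, params, grid, check = TRUE, tol = 1e-10) {
  stopifnot(inherits(params, "channel_params"), inherits(grid, "channel_grid"))
  eta <- grid$eta
  neta <- grid$neta; nx <- grid$nx
  a2Ri <- params$alpha^2 * params$Ri

  if (params$Ri == 0 || !any(c_field != 0)) {
    z <- matrix(0, neta, nx)
    return(structure(
      list(u_b = z, v_b = z, psi_b = z, m = numeric(nx), dpb_dx = numeric(nx),
           Q_b = 0, Q_b_closed = 0, grid = grid, params = params),
      class = "buoyancy_flow"
    ))
  }

  w <- eta * (1 - eta)
  Hm <- matrix(grid$H, neta, nx, byrow = TRUE)
  cumC <- cumtrapz_uniform(c_field, grid$deta)
  cumCeta <- cumtrapz_uniform(c_field * eta, grid$deta)
  I1 <- trapz_uniform(c_field * (1 - eta), grid$deta)
  A_c <- eta * cumC - cumCeta - outer(eta, I1)

  # Discretely consistent closure: the moment profile, the end-pressure
  # constant and the pressure gradient are built from the same trapezoid
  # sums that appear in the section flux of uB, so the flux is x-independent
  # to round-off on every grid, converging to the analytic closure
  # (1/Ri) dpB/dx = (6/H^3) [ int H^-3 m dx / (n int_0^1 H^-3 dx) - m ].
  t_w <- trapz_uniform(w, grid$deta)
  m <- -grid$H^3 * trapz_uniform(A_c, grid$deta) / (3 * t_w)
  Hm3 <- grid$H^-3
  K <- trapz_uniform(Hm3 * m, grid$dx) / trapz_uniform(Hm3, grid$dx)
  dpb_over_Ri <- (6 * Hm3) * (K - m)
  u_b <- a2Ri * Hm^2 * (-outer(w / 2, dpb_over_Ri) + A_c)

  psi_b <- Hm * cumtrapz_uniform(u_b, grid$deta)
  flux <- psi_b[neta, ] # integral_0^H uB dy at every x
  Q_b <- mean(flux)
  Q_b_closed <- -3 * a2Ri * t_w * K
  if (check) {
    scale <- abs(a2Ri) * max(abs(m)) + 1e-300
    if (max(abs(flux - Q_b_closed)) > tol * scale) {
      stop(sprintf(paste0("buoyancy flow rate inconsistent: section flux ",
                          "varies by %.3e about closed-form Q_B = %.6e ",
                          "(quadrature/sign bug guard)."),
                   max(abs(flux - Q_b_closed)), Q_b_closed))
    }
  }
  # vB from continuity; full-channel fields are not periodic in x
  v_b <- -deriv_x_onesided(psi_b, grid$dx) + outer(eta, grid$Hx) * u_b

  structure(
    list(u_b = u_b, v_b = v_b, psi_b = psi_b, m = m,
         dpb_dx = params$Ri * dpb_over_Ri, Q_b = Q_b, Q_b_closed = Q_b_closed,
         grid = grid, params = params),
    class = "buoyancy_flow"
  )
}

#' @export
print.buoyancy_flow <- function(x, ...) {
  cat("<buoyancy_flow>\n")
  cat(sprintf("  Ri = %g, alpha = %g; Q_B = %.6g (closed form %.6g)\n",
              x$params$Ri, x$params$alpha, x$Q_b, x$Q_b_closed))
  invisible(x)
}
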