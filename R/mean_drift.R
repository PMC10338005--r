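# Time-averaged buoyancy-free mean flow on one wavelength cell.
#
# The oscillatory flow forces a steady Eulerian drift (steady streaming)
# through the time-averaged convective acceleration, and contributes a Stokes
# drift to the mean Lagrangian velocity. Both are O(stroke-length ratio) and
# are the fields that advect the solute in the averaged transport equation.

# Mapped x-derivative at fixed y: d/dx|_y = d/dx|_eta - (eta H'/H) d/deta,
# for cell-periodic fields on the closed one-cell grid.
mapped_dx_periodic <- function(A, grid) {
  etaHxoH <- outer(grid$eta, grid$Hx / grid$H)
  deriv_x_periodic(A, grid$dx) - etaHxoH * deriv_eta(A, grid$deta)
}

mapped_dy <- function(A, grid) {
  deriv_eta(A, grid$deta) / matrix(grid$H, grid$neta, grid$nx, byrow = TRUE)
}

#' Time-averaged Reynolds forcing of the steady streaming
#'
#' `F = (1/2) Re[ d/dx (U conj(U)) + d/dy (V conj(U)) ]`, the period average
#' of the convective acceleration of the oscillatory flow. Antisymmetric about
#' the cell midplane `x = 1/2`; identically zero for a flat-walled channel.
#'
#' @param base An [oscillatory_flow()] object.
#' @return Real `[neta, nx]` matrix on the one-cell grid.
#' @export
reynolds_forcing <- function(base) {
  stopifnot(inherits(base, "oscillatory_flow"))
  g <- base$grid
  0.5 * Re(mapped_dx_periodic(base$U * Conj(base$U), g) +
             mapped_dy(base$V * Conj(base$U), g))
}

#' Stokes-drift velocity of the oscillatory flow
#'
#' `u_SD = (1/2) Im[d/dx (U conj(U)) + d/dy (V conj(U))]` and
#' `v_SD = (1/2) Im[d/dx (U conj(V)) + d/dy (V conj(V))]`: the time-averaged
#' Lagrangian velocity contribution of the purely oscillatory field. Its
#' longitudinal component vanishes identically at `x = 0, 1/2, 1` and carries
#' zero net flux at every section.
#'
#' @inheritParams reynolds_forcing
#' @return List of real `[neta, nx]` matrices `u_sd`, `v_sd`.
#' @export
stokes_drift <- function(base) {
  stopifnot(inherits(base, "oscillatory_flow"))
  g <- base$grid
  u_sd <- 0.5 * Im(mapped_dx_periodic(base$U * Conj(base$U), g) +
                     mapped_dy(base$V * Conj(base$U), g))
  v_sd <- 0.5 * Im(mapped_dx_periodic(base$U * Conj(base$V), g) +
                     mapped_dy(base$V * Conj(base$V), g))
  list(u_sd = u_sd, v_sd = v_sd)
}

#' Steady-streaming velocity and pressure gradient
#'
#' Integrates the time-averaged momentum balance driven by the Reynolds
#' forcing `F` under no-slip walls and the zero-net-flux closure:
#' `dpSS/dx = -6 H^{-3} integral_0^H F y (H - y) dy`, the quadrature-form
#' longitudinal velocity, and `vSS` from continuity. The section flux of
#' `uSS` vanishes identically (checked at run time).
#'
#' @inheritParams reynolds_forcing
#' @param forcing Optional precomputed [reynolds_forcing()] matrix.
#' @param flux_tol Tolerance for the zero-net-flux consistency check,
#'   relative to the largest `|uSS|` (quadrature/sign bug guard).
#' @return List with `u_ss`, `v_ss` (`[neta, nx]`), profile `dpss_dx`,
#'   and `psi_ss` (streamfunction, zero on the flat wall).
#' @export
steady_streaming <- function(base, forcing = NULL, flux_tol = 1e-6) {
  stopifnot(inherits(base, "oscillatory_flow"))
  g <- base$grid
  if (is.null(forcing)) forcing <- reynolds_forcing(base)
  eta <- g$eta
  a2 <- base$params$alpha^2
  Hm <- matrix(g$H, g$neta, g$nx, byrow = TRUE)
  w <- eta * (1 - eta)

  cumF <- cumtrapz_uniform(forcing, g$deta)
  cumFeta <- cumtrapz_uniform(forcing * eta, g$deta)
  I1 <- trapz_uniform(forcing * (1 - eta), g$deta)
  A_F <- eta * cumF - cumFeta - outer(eta, I1)
  # Discrete form of dpSS/dx = -6 H^-3 int F y (H-y) dy: the weight integral
  # and the forcing integrals use the same trapezoid, so the zero-net-flux
  # closure holds to round-off on every grid (and converges to the analytic
  # closure at the quadrature order).
  t_w <- trapz_uniform(w, g$deta)
  dpss_dx <- 2 * trapz_uniform(A_F, g$deta) / t_w
  u_ss <- a2 * Hm^2 * (-outer(w / 2, dpss_dx) + A_F)

  psi_ss <- Hm * cumtrapz_uniform(u_ss, g$deta)
  # zero-net-flux theorem: psi at the wavy wall is the section flux
  flux <- max(abs(psi_ss[g$neta, ]))
  scale <- max(abs(u_ss), 1e-300)
  if (flux > flux_tol * max(1, scale)) {
    stop(sprintf(paste0("steady streaming carries nonzero net flux ",
                        "(max |Q_SS| = %.3e): quadrature or sign ",
                        "inconsistency."), flux))
  }
  v_ss <- -deriv_x_periodic(psi_ss, g$dx) + outer(eta, g$Hx) * u_ss
  list(u_ss = u_ss, v_ss = v_ss, dpss_dx = dpss_dx, psi_ss = psi_ss)
}

#' Mean Lagrangian drift fields on one wavelength cell
#'
#' Convenience constructor computing the oscillatory base flow, the Reynolds
#' forcing, the steady streaming and the Stokes drift on a one-cell mapped
#' grid. These steady, cell-periodic fields are what the transport solver
#' tiles along the channel.
#'
#' @param params A [channel_params()] object (`Ri`, `sigma`, `n` ignored here).
#' @param nx_cell,neta Cell grid resolution.
#' @return Object of class `"mean_drift"`: matrices `forcing`, `u_ss`, `v_ss`,
#'   `u_sd`, `v_sd`, profile `dpss_dx`, plus the base flow and grid.
#' @examples
#' md <- mean_drift(channel_params(alpha = 4, beta = 0.4), 64, 65)
#' max(abs(md$u_ss + md$u_sd)) # peak mean Lagrangian speed
#' @export
mean_drift <- function(params, nx_cell = 200, neta = 101) {
  base <- oscillatory_flow(params, cell_grid(params, nx_cell, neta))
  forcing <- reynolds_forcing(base)
  ss <- steady_streaming(base, forcing)
  sd <- stokes_drift(base)
  structure(
    c(list(forcing = forcing), ss, sd,
      list(base = base, grid = base$grid, params = params)),
    class = "mean_drift"
  )
}

#' @export
print.mean_drift <- function(x, ...) {
  cat("<mean_drift>\n")
  cat(sprintf("  alpha = %g, beta = %g; cell grid %d x %d\n",
              x$params$alpha, x$params$beta, x$grid$nx, x$grid$neta))
  cat(sprintf("  max |u_SS| = %.4g, max |u_SD| = %.4g\n",
              max(abs(x$u_ss)), max(abs(x$u_sd))))
  invisible(x)
}

#' Streamfunction/vorticity diagnostics of a mean velocity field
#'
#' For a longitudinal mean velocity `u` on the mapped grid, computes the
#' streamfunction `psi(x, y) = integral_0^y u dy'` (so `psi = 0` on the flat
#' wall, and on both walls for zero-flux fields) and the slender-flow
#' vorticity `Omega = -du/dy`, together with a peak table (value, location,
#' sign) for each.
#'
#' @param u Real `[neta, nx]` velocity matrix.
#' @param grid The [channel_grid()] the field lives on.
#' @param label Optional field label carried into the peak table.
#' @return Object of class `"flow_diagnostics"`: matrices `psi`, `omega` and a
#'   tibble `peaks` with columns `quantity`, `value` (signed), `abs_value`,
#'   `x`, `y`.
#' @export
flow_diagnostics <- function(u, grid, label = "u") {
  stopifnot(is.matrix(u), nrow(u) == grid$neta, ncol(u) == grid$nx)
  Hm <- matrix(grid$H, grid$neta, grid$nx, byrow = TRUE)
  psi <- Hm * cumtrapz_uniform(u, grid$deta)
  omega <- -deriv_eta(u, grid$deta) / Hm
  peak_of <- function(A, quantity) {
    k <- which.max(abs(A))
    j <- (k - 1L) %/% nrow(A) + 1L
    i <- k - (j - 1L) * nrow(A)
    tibble::tibble(field = label, quantity = quantity,
                   value = A[i, j], abs_value = abs(A[i, j]),
                   x = grid$x[j], y = grid$eta[i] * grid$H[j])
  }
  structure(
    list(psi = psi, omega = omega,
         peaks = dplyr::bind_rows(peak_of(psi, "psi"), peak_of(omega, "omega")),
         grid = grid, label = label),
    class = "flow_diagnostics"
  )
}

#' Grid-converged peak streamfunction and vorticity of the mean drift
#'
#' Evaluates `max |psi|` and `max |Omega|` for the steady-streaming field
#' and/or the combined mean Lagrangian field (`u_SS + u_SD`) on a ladder of
#' grids refined by factors of two until both peaks change by less than
#' `tol` (relative), and reports the converged values. Because the fields
#' occur in antisymmetric pairs about the cell midplane, peaks come in
#' `+/-` pairs; magnitudes are reported.
#'
#' @param params A [channel_params()] object (`alpha`, `beta` used).
#' @param fields Character subset of `c("streaming", "lagrangian")`.
#' @param tol Relative change between consecutive ladder rungs at which the
#'   peak is declared converged (default 0.001, i.e. 0.1%).
#' @param nx_cell,neta Coarsest rung of the refinement ladder.
#' @param max_refine Maximum number of doublings.
#' @return Tibble with one row per field: `field`, `psi_peak`, `omega_peak`,
#'   `nx_cell`, `neta`, `converged`.
#' @examples
#' \donttest{
#' drift_peaks(channel_params(alpha = 4, beta = 0.4), fields = "streaming")
#' }
#' @export
drift_peaks <- function(params,
                        fields = c("streaming", "lagrangian"),
                        tol = 1e-3, nx_cell = 96, neta = 97,
                        max_refine = 4L) {
  fields <- match.arg(fields, several.ok = TRUE)
  prev <- NULL
  out <- NULL
  nxc <- nx_cell; ne <- neta
  for (lev in 0:max_refine) {
    md <- mean_drift(params, nxc, ne)
    cur <- purrr::map_dfr(fields, function(f) {
      u <- if (f == "streaming") md$u_ss else md$u_ss + md$u_sd
      dg <- flow_diagnostics(u, md$grid, label = f)
      tibble::tibble(field = f,
                     psi_peak = dg$peaks$abs_value[dg$peaks$quantity == "psi"],
                     omega_peak = dg$peaks$abs_value[dg$peaks$quantity == "omega"])
    })
    if (!is.null(prev)) {
      rel <- max(abs(cur$psi_peak / prev$psi_peak - 1),
                 abs(cur$omega_peak / prev$omega_peak - 1))
      if (rel < tol) {
        out <- dplyr::mutate(cur, nx_cell = nxc, neta = ne, converged = TRUE)
        break
      }
    }
    prev <- cur
    if (lev == max_refine) {
      out <- dplyr::mutate(cur, nx_cell = nxc, neta = ne, converged = FALSE)
    }
    nxc <- nxc * 2L
    ne <- 2L * (ne - 1L) + 1L
  }
  out
}
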