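# Broom-style accessors: long-format tibbles for the field objects and
# one-row summaries for fitted/simulated results.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom rlang %||%
NULL

grid_tibble <- function(grid) {
  tidyr::expand_grid(x = grid$x, eta = grid$eta) |>
    dplyr::mutate(H = channel_width(.data$x, grid$beta),
                  y = .data$eta * .data$H)
}

field_value <- function(A, grid) {
  # expand_grid(x, eta) varies eta fastest; A is [neta, nx] (eta down rows)
  as.vector(A)[(rep(seq_len(grid$nx), each = grid$neta) - 1L) * grid$neta +
                 rep(seq_len(grid$neta), grid$nx)]
}

#' Tidy the oscillatory base flow
#'
#' @param x An [oscillatory_flow()] object.
#' @param ... Unused.
#' @return Long tibble with one row per grid node: `x`, `eta`, `y`, `H`, and
#'   the complex amplitudes split into `u_re`, `u_im`, `v_re`, `v_im`.
#' @export
tidy.oscillatory_flow <- function(x, ...) {
  obj <- x
  g <- obj$grid
  grid_tibble(g) |>
    dplyr::mutate(u_re = field_value(Re(obj$U), g),
                  u_im = field_value(Im(obj$U), g),
                  v_re = field_value(Re(obj$V), g),
                  v_im = field_value(Im(obj$V), g))
}

#' @rdname tidy.oscillatory_flow
#' @export
glance.oscillatory_flow <- function(x, ...) {
  tibble::tibble(alpha = x$params$alpha, beta = x$params$beta,
                 Q_re = Re(x$Q), Q_im = Im(x$Q), Q_mod = Mod(x$Q),
                 nx_cell = x$grid$nx_cell, neta = x$grid$neta)
}

#' Tidy the mean Lagrangian drift fields
#'
#' @param x A [mean_drift()] object.
#' @param ... Unused.
#' @return Long tibble: `x`, `eta`, `y`, `H`, `u_ss`, `v_ss`, `u_sd`,
#'   `v_sd`, `u_lagr = u_ss + u_sd`, `v_lagr`, and the forcing `F`.
#' @export
tidy.mean_drift <- function(x, ...) {
  obj <- x
  g <- obj$grid
  grid_tibble(g) |>
    dplyr::mutate(u_ss = field_value(obj$u_ss, g),
                  v_ss = field_value(obj$v_ss, g),
                  u_sd = field_value(obj$u_sd, g),
                  v_sd = field_value(obj$v_sd, g),
                  u_lagr = .data$u_ss + .data$u_sd,
                  v_lagr = .data$v_ss + .data$v_sd,
                  forcing = field_value(obj$forcing, g))
}

#' @rdname tidy.mean_drift
#' @export
glance.mean_drift <- function(x, ...) {
  dg_ss <- flow_diagnostics(x$u_ss, x$grid, "streaming")
  dg_l <- flow_diagnostics(x$u_ss + x$u_sd, x$grid, "lagrangian")
  tibble::tibble(
    alpha = x$params$alpha, beta = x$params$beta,
    psi_peak_ss = dg_ss$peaks$abs_value[1L],
    omega_peak_ss = dg_ss$peaks$abs_value[2L],
    psi_peak_lagr = dg_l$peaks$abs_value[1L],
    omega_peak_lagr = dg_l$peaks$abs_value[2L],
    nx_cell = x$grid$nx_cell, neta = x$grid$neta)
}

#' Tidy the buoyancy-induced mean flow
#'
#' @param x A [buoyancy_flow()] object.
#' @param ... Unused.
#' @return Long tibble: `x`, `eta`, `y`, `H`, `u_b`, `v_b`, `psi_b`.
#' @export
tidy.buoyancy_flow <- function(x, ...) {
  obj <- x
  g <- obj$grid
  grid_tibble(g) |>
    dplyr::mutate(u_b = field_value(obj$u_b, g),
                  v_b = field_value(obj$v_b, g),
                  psi_b = field_value(obj$psi_b, g))
}

#' @rdname tidy.buoyancy_flow
#' @export
glance.buoyancy_flow <- function(x, ...) {
  tibble::tibble(alpha = x$params$alpha, Ri = x$params$Ri,
                 Q_b = x$Q_b, Q_b_closed = x$Q_b_closed,
                 dpb_dx_max = max(abs(x$dpb_dx)))
}

#' Tidy a transport simulation
#'
#' @param x A [run_transport()] result.
#' @param what `"profiles"` (default; per-snapshot solute-per-unit-length and
#'   flux profiles), `"diagnostics"`, `"cells"` (per-cell masses) or
#'   `"fields"` (long-format concentration snapshots, if retained).
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.transport_run <- function(x, what = c("profiles", "diagnostics",
                                           "cells", "fields"), ...) {
  what <- match.arg(what)
  if (what == "profiles") return(x$profiles)
  if (what == "diagnostics") return(x$diagnostics)
  if (what == "cells") return(x$cell_mass)
  obj <- x
  purrr::imap_dfr(obj$fields, function(cf, tau) {
    grid_tibble(obj$grid) |>
      dplyr::mutate(tau = as.numeric(tau), c = field_value(cf, obj$grid))
  })
}

#' @rdname tidy.transport_run
#' @export
glance.transport_run <- function(x, ...) {
  d <- x$diagnostics
  nlast <- nrow(d)
  tibble::tibble(
    alpha = x$params$alpha, beta = x$params$beta, Ri = x$params$Ri,
    sigma = x$params$sigma, n = x$params$n,
    tau_end = x$tau_end, n_steps = x$n_steps,
    M0 = d$M[1L], mass_drift = abs(d$M[nlast] / d$M[1L] - 1),
    Q_b_final = d$Q_b[nlast], x_com_final = d$x_com[nlast],
    c_min = min(d$c_min), c_max = max(d$c_max))
}

#' @rdname tidy.transport_run
#' @param x A [low_sigma_transport()] result.
#' @export
tidy.low_sigma_run <- function(x, ...) x$profiles

#' @rdname tidy.transport_run
#' @export
glance.low_sigma_run <- function(x, ...) {
  d <- x$diagnostics
  tibble::tibble(alpha = x$params$alpha, Ri = x$params$Ri,
                 M0 = d$M[1L], mass_drift = abs(d$M[nrow(d)] / d$M[1L] - 1),
                 Q_b_final = d$Q_b[nrow(d)])
}
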