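# ggplot2 visualisation: streamline-style contour maps of the mean drift,
# concentration snapshots, and flow-rate / profile series.

#' Plot mean Lagrangian drift as streamlines over vorticity
#'
#' Contours of the streamfunction at a fixed interval `dpsi` (so line
#' spacing measures local speed, as in the standard presentation of these
#' fields) over a filled vorticity map, for the chosen field.
#'
#' @param object A [mean_drift()] object.
#' @param field `"lagrangian"` (steady streaming + Stokes drift, default),
#'   `"streaming"` or `"stokes"`.
#' @param dpsi Streamfunction contour interval; default 0.003, switch to
#'   0.03 for strong-streaming cases (e.g. `alpha = 16`).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mean_drift <- function(object, field = c("lagrangian", "streaming",
                                                  "stokes"),
                                dpsi = 0.003, ...) {
  field <- match.arg(field)
  u <- switch(field,
              lagrangian = object$u_ss + object$u_sd,
              streaming = object$u_ss,
              stokes = object$u_sd)
  dg <- flow_diagnostics(u, object$grid, field)
  g <- object$grid
  df <- grid_tibble(g) |>
    dplyr::mutate(psi = field_value(dg$psi, g),
                  omega = field_value(dg$omega, g))
  lim <- max(abs(df$psi))
  breaks <- seq(-lim, lim, by = dpsi)
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$omega)) +
    ggplot2::geom_contour(ggplot2::aes(z = .data$psi), breaks = breaks,
                          colour = "black", linewidth = 0.25) +
    ggplot2::scale_fill_distiller(palette = "RdBu",
                                  limits = c(-1, 1) * max(abs(df$omega))) +
    ggplot2::coord_fixed(ratio = 0.5, expand = FALSE) +
    ggplot2::labs(x = "x (wavelengths)", y = "y (gap widths)",
                  fill = expression(Omega),
                  title = sprintf("%s drift, alpha = %g, beta = %g",
                                  field, object$params$alpha,
                                  object$params$beta))
}

#' Plot a transport run
#'
#' @param object A [run_transport()] result.
#' @param what `"profiles"` (solute per unit length `C(x)` coloured by time,
#'   default), `"qb"` (buoyancy flow-rate series) or `"field"` (concentration
#'   maps of the retained snapshots).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.transport_run <- function(object, what = c("profiles", "qb", "field"),
                                   ...) {
  what <- match.arg(what)
  if (what == "profiles") {
    return(
      ggplot2::ggplot(object$profiles,
                      ggplot2::aes(.data$x, .data$C, colour = .data$tau,
                                   group = .data$tau)) +
        ggplot2::geom_line() +
        ggplot2::scale_colour_viridis_c() +
        ggplot2::labs(x = "x (wavelengths)",
                      y = "solute per unit length C(x)",
                      colour = expression(tau))
    )
  }
  if (what == "qb") {
    return(
      ggplot2::ggplot(object$diagnostics,
                      ggplot2::aes(.data$tau, .data$Q_b)) +
        ggplot2::geom_line() +
        ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
        ggplot2::labs(x = expression(tau), y = expression(Q[B]))
    )
  }
  df <- tidy.transport_run(object, what = "fields")
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$c)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~tau, ncol = 1, labeller = ggplot2::label_both) +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1), oob = scales_squish) +
    ggplot2::coord_fixed(ratio = 0.5, expand = FALSE) +
    ggplot2::labs(x = "x (wavelengths)", y = "y (gap widths)", fill = "c")
}

# minimal squish (avoids a scales dependency for one oob rule)
scales_squish <- function(x, range = c(0, 1)) {
  pmin(pmax(x, range[1L]), range[2L])
}

#' @rdname autoplot.transport_run
#' @export
autoplot.low_sigma_run <- function(object, ...) {
  ggplot2::ggplot(object$profiles,
                  ggplot2::aes(.data$x, .data$C, colour = .data$tau,
                               group = .data$tau)) +
    ggplot2::geom_line() +
    ggplot2::scale_colour_viridis_c() +
    ggplot2::labs(x = "x (wavelengths)", y = "C(x) = H c",
                  colour = expression(tau))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
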