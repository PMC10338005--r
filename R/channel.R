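#' Dimensionless control parameters of the oscillating wavy channel
#'
#' Bundles the dimensionless groups governing pulsatile flow and solute
#' transport in a slender vertical channel bounded by a flat wall and a wavy
#' wall: the Womersley number `alpha` (ratio of transverse viscous time to
#' oscillation time), the wall-waviness amplitude `beta`, the Richardson
#' number `Ri` (buoyancy vs. convective acceleration; positive for a solute
#' lighter than the carrier fluid), the reduced Schmidt number `sigma`
#' (order-unity grouping of the very small solute diffusivity), and the number
#' of identical wavelength cells `n` making up the channel.
#'
#' @param alpha Womersley number, > 0.
#' @param beta Relative amplitude of the wall undulation, 0 <= beta < 1
#'   (the channel must never pinch shut).
#' @param Ri Richardson number; any sign. `Ri > 0` corresponds to a solute
#'   lighter than the carrier fluid (upward buoyant draft).
#' @param sigma Reduced Schmidt number, > 0.
#' @param n Number of wavelength cells (positive integer); the channel spans
#'   `x` in `[0, n]` with `x` measured downward from the upper end.
#' @param epsilon Optional stroke-length ratio. Metadata only: it never enters
#'   the reduced model, and is used solely by [cycles_from_tau()] to convert
#'   slow time to oscillation counts.
#'
#' @return An object of class `"channel_params"` (a named list).
#' @examples
#' channel_params(alpha = 4, beta = 0.2, Ri = 1, sigma = 1, n = 3)
#' @export
channel_params <- function(alpha = 4, beta = 0.2, Ri = 0, sigma = 1, n = 3,
                           epsilon = NULL) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L,
            is.numeric(beta), length(beta) == 1L,
            is.numeric(Ri), length(Ri) == 1L,
            is.numeric(sigma), length(sigma) == 1L,
            is.numeric(n), length(n) == 1L)
  if (!is.finite(alpha) || alpha <= 0) stop("`alpha` must be a positive number.")
  if (!is.finite(beta) || beta < 0 || beta >= 1) {
    stop("invalid geometry: `beta` must satisfy 0 <= beta < 1 ",
         "(beta >= 1 pinches the channel shut).")
  }
  if (!is.finite(sigma) || sigma <= 0) stop("`sigma` must be a positive number.")
  if (n < 1 || n != round(n)) stop("`n` must be a positive integer.")
  if (!is.null(epsilon)) {
    if (!is.numeric(epsilon) || length(epsilon) != 1L || epsilon <= 0) {
      stop("`epsilon` must be a positive number (or NULL).")
    }
  }
  structure(
    list(alpha = alpha, beta = beta, Ri = Ri, sigma = sigma, n = as.integer(n),
         epsilon = epsilon),
    class = "channel_params"
  )
}

#' @export
print.channel_params <- function(x, ...) {
  cat("<channel_params>\n")
  cat(sprintf("  alpha = %g  beta = %g  Ri = %g  sigma = %g  n = %d\n",
              x$alpha, x$beta, x$Ri, x$sigma, x$n))
  if (!is.null(x$epsilon)) cat(sprintf("  epsilon = %g (metadata)\n", x$epsilon))
  invisible(x)
}

#' Local channel width
#'
#' The channel occupies `0 <= y <= H(x)` with `H(x) = 1 + beta * cos(2 pi x)`,
#' so the width oscillates with unit period between `1 - beta` and `1 + beta`.
#'
#' @param x Longitudinal position(s), in wavelength units.
#' @param beta Wall-waviness amplitude, 0 <= beta < 1.
#' @return Numeric vector `H(x)`.
#' @examples
#' channel_width(c(0, 0.25, 0.5), beta = 0.4) # 1.4, 1.0, 0.6
#' @export
channel_width <- function(x, beta) {
  if (!is.numeric(beta) || length(beta) != 1L || beta < 0 || beta >= 1) {
    stop("invalid geometry: `beta` must satisfy 0 <= beta < 1.")
  }
  1 + beta * cos(2 * pi * x)
}

# dH/dx, used by all mapped-coordinate metric terms
channel_width_slope <- function(x, beta) {
  -2 * pi * beta * sin(2 * pi * x)
}

#' Uniform computational grid in mapped coordinates
#'
#' Builds the closed tensor grid used throughout: `x` uniform on `[0, n]`
#' (endpoints included, `n * nx_cell + 1` points) and the wall-normalised
#' transverse coordinate `eta = y / H(x)` uniform on `[0, 1]` (`neta` points).
#' Mapping the wavy gap onto the unit interval lets boundary conditions sit on
#' grid nodes and makes every transverse integral a fixed-interval quadrature.
#'
#' @param params A [channel_params()] object (only `n` and `beta` are used).
#' @param nx_cell Points per wavelength cell in `x` (>= 16).
#' @param neta Points across the gap in `eta` (>= 9).
#' @return An object of class `"channel_grid"`: `x`, `eta`, spacings
#'   `dx`, `deta`, the per-node width `H` and slope `Hx`, and the sizes.
#' @examples
#' g <- channel_grid(channel_params(n = 1), nx_cell = 16, neta = 9)
#' length(g$x) # 17
#' @export
channel_grid <- function(params, nx_cell = 200, neta = 101) {
  stopifnot(inherits(params, "channel_params"))
  if (nx_cell < 16) stop("`nx_cell` must be at least 16.")
  if (neta < 9) stop("`neta` must be at least 9.")
  nx_cell <- as.integer(nx_cell)
  neta <- as.integer(neta)
  n <- params$n
  nx <- n * nx_cell + 1L
  x <- seq(0, n, length.out = nx)
  eta <- seq(0, 1, length.out = neta)
  structure(
    list(x = x, eta = eta,
         dx = n / (nx - 1L), deta = 1 / (neta - 1L),
         nx = nx, neta = neta, nx_cell = nx_cell, n = n,
         beta = params$beta,
         H = channel_width(x, params$beta),
         Hx = channel_width_slope(x, params$beta)),
    class = "channel_grid"
  )
}

# One-cell restriction of a grid: x in [0, 1], nx_cell + 1 points.
# Cell-periodic fields (base flow, steady streaming, Stokes drift) are
# computed here and tiled to the full channel.
cell_grid <- function(params, nx_cell = 200, neta = 101) {
  p1 <- params
  p1$n <- 1L
  channel_grid(p1, nx_cell = nx_cell, neta = neta)
}

#' Composite trapezoidal rule on a uniform grid
#'
#' The quadrature used throughout the model for every transverse and
#' longitudinal integral. Exact for affine integrands; second-order accurate
#' for smooth ones.
#'
#' @param values Sampled integrand: a vector, or a matrix integrated down its
#'   rows (one result per column).
#' @param spacing Uniform sample spacing.
#' @return Scalar (vector input) or one value per column (matrix input).
#' @examples
#' trapz_uniform(rep(1, 11), 0.1) # 1
#' trapz_uniform(seq(0, 1, 0.25), 0.25) # 0.5
#' @export
trapz_uniform <- function(values, spacing) {
  if (is.matrix(values)) {
    m <- nrow(values)
    if (m < 2L) stop("trapezoidal rule needs at least 2 samples.")
    return(spacing * (colSums(values) - (values[1L, ] + values[m, ]) / 2))
  }
  m <- length(values)
  if (m < 2L) stop("trapezoidal rule needs at least 2 samples.")
  spacing * (sum(values) - (values[1L] + values[m]) / 2)
}

#' Cumulative trapezoidal integral on a uniform grid
#'
#' @inheritParams trapz_uniform
#' @return Same shape as `values`; the running integral from the first sample
#'   (matrix input: cumulated down each column).
#' @export
cumtrapz_uniform <- function(values, spacing) {
  if (is.matrix(values)) {
    m <- nrow(values)
    if (m < 2L) stop("trapezoidal rule needs at least 2 samples.")
    avg <- (values[-1L, , drop = FALSE] + values[-m, , drop = FALSE]) / 2
    # running column sums as a lower-triangular matmul (BLAS beats apply())
    L <- matrix(0, m - 1L, m - 1L)
    L[row(L) >= col(L)] <- 1
    out <- rbind(0, (L %*% avg) * spacing)
    dimnames(out) <- NULL
    return(out)
  }
  m <- length(values)
  if (m < 2L) stop("trapezoidal rule needs at least 2 samples.")
  c(0, cumsum((values[-1L] + values[-m]) / 2) * spacing)
}
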