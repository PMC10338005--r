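# Leading-order oscillatory (Womersley-type) flow in the wavy channel.
#
# The physical fields are recovered from the complex amplitudes as
#   u0 = Re(i e^{it} U),  v0 = Re(i e^{it} V),  p0 = Re(e^{it} P),
# with U = dP/dx * G(x, y) a Womersley profile in the local gap and V obtained
# from continuity. The local Stokes-layer parameter Lambda satisfies
# Lambda^2 = i alpha^2 H^2 / 4 (branch with positive real part), as follows
# from substituting the profile into the longitudinal momentum balance
# -U = -dP/dx + (i/alpha^2) d2U/dy2.

#' Local Stokes-layer (Womersley) parameter
#'
#' `Lambda(x) = (alpha H(x) / 2) * (1 + 1i) / sqrt(2)`, the square root of
#' `i alpha^2 H^2 / 4` with positive real part. Only `Lambda^2` enters the
#' velocity profile (cosh is even), but the branch fixes the sign of the
#' Stokes drift downstream, so it is pinned by the momentum-residual identity
#' rather than left to the square root.
#'
#' @param x Longitudinal position(s).
#' @param params A [channel_params()] object.
#' @return Complex vector `Lambda(x)` with `Mod(Lambda) = alpha H / 2`.
#' @export
womersley_lambda <- function(x, params) {
  stopifnot(inherits(params, "channel_params"))
  H <- channel_width(x, params$beta)
  (params$alpha * H / 2) * complex(real = 1, imaginary = 1) / sqrt(2)
}

#' Womersley velocity profile function
#'
#' `G = 1 - cosh(Lambda (2 y / H - 1)) / cosh(Lambda)`, the complex transverse
#' shape of the oscillatory longitudinal velocity `U = dP/dx * G`. Vanishes at
#' both walls; tends to the parabolic (Poiseuille) shape scaled by
#' `Lambda^2 / 2` as `alpha -> 0`.
#'
#' @param x Longitudinal position (scalar or vector).
#' @param y Transverse position(s), `0 <= y <= H(x)`.
#' @inheritParams womersley_lambda
#' @return Complex `G(x, y)`, recycled over the longer of `x`, `y`.
#' @export
profile_G <- function(x, y, params) {
  H <- channel_width(x, params$beta)
  if (any(y < -1e-12 | y > H + 1e-12)) {
    stop("`y` outside the channel: need 0 <= y <= H(x).")
  }
  L <- womersley_lambda(x, params)
  1 - cosh(L * (2 * y / H - 1)) / cosh(L)
}

# Guard against cosh overflow (|Lambda| ~ alpha H / 2; double cosh overflows
# near 710, so the model range alpha <= 16 is far from trouble).
check_lambda_range <- function(params) {
  if (params$alpha * (1 + params$beta) / 2 > 300) {
    stop("`alpha` too large for direct cosh evaluation of the Womersley ",
         "profile (overflow); this model targets alpha of order 1-20.")
  }
}

#' Oscillatory flow rate and pressure gradient
#'
#' The complex flow-rate amplitude and pressure-gradient profile of the
#' leading-order oscillatory flow, fixed by the end conditions `P(0) = 0`,
#' `P(n) = n`:
#' `Q = [ integral_0^1 dx / (H (1 - tanh(Lambda)/Lambda)) ]^{-1}` and
#' `dP/dx = Q / (H (1 - tanh(Lambda)/Lambda))`, both independent of the
#' number of cells `n`.
#'
#' @inheritParams womersley_lambda
#' @param grid A one-cell [channel_grid()] (or any grid; only its cell
#'   resolution is used).
#' @return List with complex scalar `Q`, complex profile `dPdx` on the
#'   one-cell closed grid, and the one-cell `x` vector it is sampled on.
#' @export
flow_rate_and_pressure <- function(params, grid = NULL) {
  stopifnot(inherits(params, "channel_params"))
  check_lambda_range(params)
  if (is.null(grid)) grid <- cell_grid(params)
  nxc <- grid$nx_cell
  x1 <- seq(0, 1, length.out = nxc + 1L)
  H1 <- channel_width(x1, params$beta)
  L1 <- womersley_lambda(x1, params)
  denom <- H1 * (1 - tanh(L1) / L1)
  Q <- 1 / trapz_uniform(1 / denom, 1 / nxc)
  list(Q = Q, dPdx = Q / denom, x = x1)
}

#' Leading-order oscillatory base flow on a one-cell grid
#'
#' Assembles the complex amplitude fields of the Womersley-type oscillatory
#' flow: `U = dP/dx * G`, its wall-to-`y` integral (closed form), and the
#' transverse component `V = -d/dx integral_0^y U dy'` evaluated with
#' fourth-order periodic differencing in `x` at fixed `y`. All fields are
#' cell-periodic and are stored on the mapped `(x, eta)` tensor grid as
#' `[neta, nx]` matrices.
#'
#' @inheritParams womersley_lambda
#' @param grid Optional one-cell [channel_grid()]; defaults to a
#'   200 x 101 cell grid.
#' @return An object of class `"oscillatory_flow"` with complex matrices
#'   `U`, `V`, `IG` (the running integral of `U`), profiles `dPdx`,
#'   `Lambda`, scalar `Q`, and the grid.
#' @examples
#' bf <- oscillatory_flow(channel_params(alpha = 4, beta = 0.4, n = 1))
#' max(Mod(bf$U[c(1, nrow(bf$U)), ])) # no-slip: 0 at both walls
#' @export
oscillatory_flow <- function(params, grid = NULL) {
  stopifnot(inherits(params, "channel_params"))
  check_lambda_range(params)
  if (is.null(grid)) grid <- cell_grid(params)
  if (grid$n != 1L) grid <- cell_grid(params, grid$nx_cell, grid$neta)

  x <- grid$x; eta <- grid$eta
  H <- grid$H; Hx <- grid$Hx
  neta <- grid$neta; nx <- grid$nx

  L <- womersley_lambda(x, params)
  fp <- flow_rate_and_pressure(params, grid)
  dPdx <- fp$dPdx; Q <- fp$Q

  s <- 2 * eta - 1 # symmetric transverse coordinate
  arg <- outer(s, L) # [neta, nx]
  coshL <- matrix(cosh(L), neta, nx, byrow = TRUE)
  Hm <- matrix(H, neta, nx, byrow = TRUE)
  Pm <- matrix(dPdx, neta, nx, byrow = TRUE)
  Lm <- matrix(L, neta, nx, byrow = TRUE)

  G <- 1 - cosh(arg) / coshL
  U <- Pm * G
  # integral_0^y G dy' = y - (H / 2 Lambda) (sinh(arg) + sinh(Lambda)) / cosh(Lambda)
  y <- outer(eta, H)
  sinhL <- matrix(sinh(L), neta, nx, byrow = TRUE)
  intG <- y - (Hm / (2 * Lm)) * (sinh(arg) + sinhL) / coshL
  IG <- Pm * intG

  # V = -d/dx|_y IG = -d/dx|_eta IG + eta H' U  (since d/deta IG = H U)
  etaHx <- outer(eta, Hx)
  V <- -deriv_x_periodic(IG, grid$dx) + etaHx * U

  structure(
    list(U = U, V = V, IG = IG, G = G, dPdx = dPdx, Q = Q, Lambda = L,
         grid = grid, params = params),
    class = "oscillatory_flow"
  )
}

#' @export
print.oscillatory_flow <- function(x, ...) {
  cat("<oscillatory_flow>\n")
  cat(sprintf("  alpha = %g, beta = %g; cell grid %d x %d\n",
              x$params$alpha, x$params$beta, x$grid$nx, x$grid$neta))
  cat(sprintf("  Q = %.6f %+.6fi\n", Re(x$Q), Im(x$Q)))
  invisible(x)
}
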