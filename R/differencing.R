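# Finite-difference kernels shared by the mean-flow and transport modules.
# Field matrices are [neta, nx]: eta down the rows, x across the columns.

# 4th-order derivative along the row coordinate (down each column), uniform
# spacing h; 5-point one-sided closures at the two rows nearest each boundary.
fd4_rows <- function(A, h) {
  if (is.null(dim(A))) A <- matrix(A, ncol = 1L)
  m <- nrow(A)
  if (m < 5L) stop("fd4_rows needs at least 5 points.")
  D <- A # shape template
  i <- 3:(m - 2L)
  D[i, ] <- (A[i - 2L, , drop = FALSE] - 8 * A[i - 1L, , drop = FALSE] +
               8 * A[i + 1L, , drop = FALSE] - A[i + 2L, , drop = FALSE]) / (12 * h)
  D[1L, ] <- (-25 * A[1L, ] + 48 * A[2L, ] - 36 * A[3L, ] +
                16 * A[4L, ] - 3 * A[5L, ]) / (12 * h)
  D[2L, ] <- (-3 * A[1L, ] - 10 * A[2L, ] + 18 * A[3L, ] -
                6 * A[4L, ] + A[5L, ]) / (12 * h)
  D[m - 1L, ] <- (3 * A[m, ] + 10 * A[m - 1L, ] - 18 * A[m - 2L, ] +
                    6 * A[m - 3L, ] - A[m - 4L, ]) / (12 * h)
  D[m, ] <- (25 * A[m, ] - 48 * A[m - 1L, ] + 36 * A[m - 2L, ] -
               16 * A[m - 3L, ] + 3 * A[m - 4L, ]) / (12 * h)
  D
}

# Derivative with respect to eta (row coordinate).
deriv_eta <- function(A, deta) fd4_rows(A, deta)

# 4th-order derivative with respect to x (column coordinate) for CELL-PERIODIC
# fields sampled on a closed one-cell grid (first and last columns coincide).
deriv_x_periodic <- function(A, dx) {
  nx <- ncol(A)
  m <- nx - 1L # unique columns
  if (m < 5L) stop("periodic x-differencing needs at least 5 unique points.")
  idx <- function(k) ((seq_len(m) - 1L + k) %% m) + 1L
  B <- A[, seq_len(m), drop = FALSE]
  D <- (B[, idx(-2L), drop = FALSE] - 8 * B[, idx(-1L), drop = FALSE] +
          8 * B[, idx(1L), drop = FALSE] - B[, idx(2L), drop = FALSE]) / (12 * dx)
  cbind(D, D[, 1L, drop = FALSE])
}

# Non-periodic x-derivative (full-channel fields): 4th order with one-sided
# closures, reusing the row kernel via transposition.
deriv_x_onesided <- function(A, dx) t(fd4_rows(t(A), dx))

# x-derivative of a full-channel field assembled by tiling a cell-periodic
# field: interior treated periodically cell-by-cell is wrong at the channel
# scale only if the field is not truly periodic, so callers choose explicitly.
# (Helper kept for symmetry of the API.)

# Tile a closed one-cell field [neta, nx_cell + 1] to the closed full-channel
# grid [neta, n * nx_cell + 1] (first column == last column of each cell).
tile_cell_field <- function(A, n) {
  if (n == 1L) return(A)
  m <- ncol(A) - 1L
  core <- A[, seq_len(m), drop = FALSE]
  out <- do.call(cbind, rep(list(core), n))
  cbind(out, A[, m + 1L, drop = FALSE])
}

# Tile a closed one-cell x-profile (length nx_cell + 1) to the full channel.
tile_cell_profile <- function(v, n) {
  if (n == 1L) return(v)
  m <- length(v) - 1L
  c(rep(v[seq_len(m)], n), v[m + 1L])
}
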