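# Spectral analysis of the sine-law gravitropic system
#
#   kappa_dot = -beta sin(theta) - gamma kappa,   theta' = kappa
#
# on a space-time rectangle, with the base clamped.  For gamma > 0 the
# proprioceptive damping suppresses the lateral oscillations of the upward
# growth; for gamma < 0 ("negative proprioception") the vertical equilibrium
# is unstable and the stem curls.

#' Simulate the sine-law system
#'
#' Method of lines: `theta(s, t) = theta0 + integral of kappa` (trapezoid on
#' the grid, clamp `theta(0, t) = theta0`), and the curvature field integrated
#' in time with `deSolve::ode`. The initial intrinsic curvature is the
#' constant `kappa0`, so the initial shape is a circular arc (straight rod for
#' `kappa0 = 0`).
#'
#' @param beta stimulus gain.
#' @param gamma proprioceptive gain (sign free).
#' @param S_len spatial extent, default 1.
#' @param T_len final time, default 2.
#' @param theta0 clamp angle, rad.
#' @param kappa0 initial curvature (scalar or vector on the grid).
#' @param n number of grid intervals.
#' @param n_out number of stored time slices.
#' @return List with `s` (grid), `times`, `theta` (matrix, time x space),
#'   `kappa` (same shape).
#' @export
simulate_sine_law <- function(beta, gamma, S_len = 1, T_len = 2,
                              theta0 = 0, kappa0 = 0, n = 200L, n_out = 41L) {
  stopifnot(S_len > 0, T_len > 0, n >= 8L)
  s <- seq(0, S_len, length.out = n + 1L)
  h <- diff(s)
  k0 <- rep_len(kappa0, n + 1L)
  theta_of <- function(k)
    theta0 + cumsum(c(0, h * (k[-length(k)] + k[-1]) / 2))
  rhs <- function(t, k, parms) {
    th <- theta_of(k)
    if (any(!is.finite(th)) || max(abs(th)) > 1e6)
      stop("sine-law simulation blew up at t = ", format(t), call. = FALSE)
    list(-beta * sin(th) - gamma * k)
  }
  times <- seq(0, T_len, length.out = n_out)
  sol <- deSolve::ode(y = k0, times = times, func = rhs, parms = NULL,
                      method = "lsoda", rtol = 1e-8, atol = 1e-10)
  kappa <- unname(sol[, -1, drop = FALSE])
  theta <- t(apply(kappa, 1, theta_of))
  list(s = s, times = times, theta = theta, kappa = kappa)
}

#' Spectrum of the linearised sine-law operator
#'
#' Linearising the sine-law system about the vertical equilibrium gives the
#' differential-algebraic pencil
#' `[[0,0],[0,1]] d/dt (theta, kappa) = [[d/ds, -1], [-beta, -gamma]] (theta, kappa)`
#' with the clamped boundary `theta(0) = 0`. `d/ds` is discretised by
#' first-order upwind differences from the clamped end (matrix `D`). The
#' algebraic row (`kappa = D theta`) is eliminated exactly, which removes the
#' infinite eigenvalues of the pencil and leaves the finite spectrum as the
#' eigenvalues of `-beta D^{-1} - gamma I`. That matrix is lower triangular
#' (the inverse of the upwind derivative is the left-rectangle integration
#' matrix), so its spectrum is read exactly from the diagonal:
#' `-beta h - gamma` with multiplicity `n`. Reading the diagonal avoids the
#' large rounding scatter a dense nonsymmetric eigensolver produces on this
#' maximally defective matrix.
#'
#' @param beta,gamma gains of the linearised system.
#' @param n grid size (>= 8).
#' @param S_len spatial extent.
#' @return List with `values` (complex eigenvalues), `h` (grid spacing), and
#'   `matrix` (the reduced operator, materialised only for `n <= 2000`).
#' @export
linear_spectrum <- function(beta, gamma, n = 100L, S_len = 1) {
  stopifnot(n >= 8L)
  h <- S_len / n
  A <- NULL
  if (n <= 2000L) {
    # D^{-1}: lower-triangular matrix of h (cumulative left-rectangle sums)
    Dinv <- h * lower.tri(diag(n), diag = TRUE)
    A <- -beta * Dinv - gamma * diag(n)
  }
  vals <- if (!is.null(A)) as.complex(diag(A))
          else as.complex(rep(-beta * h - gamma, n))
  list(values = vals, h = h, matrix = A)
}

#' Closed-form steady state of the sine-law system
#'
#' The linearised steady state `theta' = -(beta/gamma) theta` with clamp
#' `theta(0) = theta0` gives `theta(s) = theta0 exp(-beta s / gamma)`: decay
#' to the vertical for `beta, gamma > 0`, curling growth for `gamma < 0`.
#'
#' @param theta0 clamp angle, rad.
#' @param beta,gamma gains; `gamma` must be nonzero.
#' @param s arc length(s).
#' @return `theta(s)` in rad.
#' @export
steady_state <- function(theta0, beta, gamma, s) {
  if (gamma == 0) stop("gamma must be nonzero for the steady state", call. = FALSE)
  theta0 * exp(-beta * s / gamma)
}
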