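# Static Kirchhoff balance of the heavy planar rod.  The inclination theta is
# measured from the upward vertical e2; gravity acts along -e2; the tangent is
# (sin theta, cos theta).  Equilibrium:
#
#   d/ds [ B (kappa - theta') ] = [ integral_s^ell rho dsigma + m_l(s) ] g sin theta
#
# with clamp theta(0) = theta0 and a moment-free tip, kappa(ell) = theta'(ell).
# Discretised with piecewise-linear finite elements on the (generally
# non-uniform) current mesh and solved by damped Newton iteration, with
# continuation in g as a fallback for strongly loaded rods.

# Tridiagonal solve (Thomas algorithm): sub-diagonal a, diagonal b,
# super-diagonal c, right-hand side d.
thomas_solve <- function(a, b, c, d) {
  n <- length(b)
  cp <- numeric(n); dp <- numeric(n)
  cp[1] <- c[1] / b[1]
  dp[1] <- d[1] / b[1]
  if (n > 1) for (i in 2:n) {
    m <- b[i] - a[i - 1] * cp[i - 1]
    cp[i] <- if (i < n) c[i] / m else 0
    dp[i] <- (d[i] - a[i - 1] * dp[i - 1]) / m
  }
  x <- numeric(n)
  x[n] <- dp[n]
  if (n > 1) for (i in (n - 1):1) x[i] <- dp[i] - cp[i] * x[i + 1]
  x
}

# Distributed weight per unit length at the nodes: w(s) = g * (integral of rho
# from s to the tip + leaf load above s).  The density integral uses the
# trapezoid rule on the same mesh as the FEM.
node_weights <- function(s, profiles, layout, g) {
  ell <- s[length(s)]
  x <- pmax(ell - s, 0)
  rho <- linear_density(profiles, x)
  n <- length(s)
  h <- diff(s)
  seg <- h * (rho[-n] + rho[-1]) / 2
  hang <- rev(cumsum(rev(c(seg, 0))))   # integral_s^ell rho dsigma at nodes
  ml <- leaf_load(s, layout, profiles, ell)
  g * (hang + ml)
}

#' Solve the static rod equilibrium
#'
#' Finds the inclination field `theta(s)` balancing the bending moment against
#' the hanging weight (distributed mass plus lumped leaf loads), given the
#' intrinsic curvature `kappa(s)`, the rigidity profile and the clamp angle.
#' Piecewise-linear FEM in space; damped Newton with continuation in `g` when
#' the load is too strong for a direct solve.
#'
#' @param s nodal arc lengths (increasing, first node at the clamp), m.
#' @param kappa intrinsic curvature at the nodes, m^-1.
#' @param theta0 clamp angle from the vertical, rad.
#' @param profiles a [material_profiles]; rigidity `B` and density are
#'   evaluated at the distance from tip `x = ell - s`.
#' @param layout a [leaf_layout] of lumped leaf masses (may be empty).
#' @param g gravitational acceleration, m s^-2; `g = 0` returns the intrinsic
#'   configuration (`theta' = kappa`).
#' @param theta_init optional initial guess for the Newton iteration (defaults
#'   to the intrinsic configuration).
#' @param tol residual tolerance (max-norm) for convergence.
#' @param maxit maximum Newton iterations per continuation stage.
#' @return A list with `theta` (nodal inclinations, rad), `residual` (final
#'   max-norm residual), `iterations`, and `weights` (nodal load, N m^-1).
#' @export
solve_equilibrium <- function(s, kappa, theta0, profiles, layout = leaf_layout(0, 0),
                              g = 9.81, theta_init = NULL,
                              tol = 1e-10, maxit = 50L) {
  n <- length(s)
  stopifnot(n >= 3L, length(kappa) == n, all(diff(s) > 0))
  ell <- s[n]
  h <- diff(s)
  xe <- pmax(ell - (s[-n] + s[-1]) / 2, 0)   # element midpoints, distance from tip
  Be <- profile_B(profiles, xe)
  if (any(Be <= 0)) stop("flexural rigidity must be positive along the rod", call. = FALSE)
  kbar <- (kappa[-n] + kappa[-1]) / 2
  m_lump <- c(h[1] / 2, (h[-1] + h[-(n - 1)]) / 2, h[n - 1] / 2)

  if (is.null(theta_init)) theta_init <- theta0 + cumsum(c(0, h * kbar))

  w_full <- node_weights(s, profiles, layout, g)

  # residual at the free nodes j = 2..n:  F_{j-1} - F_j - m_j w_j sin(theta_j),
  # where F_e = B_e (theta'_e - kbar_e) is the element moment flux and F_n = 0
  # (natural moment-free tip condition)
  residual <- function(theta, w) {
    Fe <- Be * (diff(theta) / h - kbar)
    Fe - c(Fe[-1], 0) - (m_lump * w * sin(theta))[-1]
  }

  q <- Be / h
  newton <- function(theta, w) {
    r <- residual(theta, w)
    for (it in seq_len(maxit)) {
      nr <- max(abs(r))
      if (nr < tol) return(list(theta = theta, residual = nr, it = it - 1L, ok = TRUE))
      dcos <- (m_lump * w * cos(theta))[-1]
      dia <- q + c(q[-1], 0) - dcos
      off <- -q[-1]                     # tridiagonal couplings (symmetric)
      step <- thomas_solve(off, dia, off, -r)
      lam <- 1
      repeat {
        theta_new <- theta
        theta_new[-1] <- theta[-1] + lam * step
        r_new <- residual(theta_new, w)
        if (max(abs(r_new)) < nr || lam < 1e-4) break
        lam <- lam / 2
      }
      theta <- theta_new
      r <- r_new
    }
    list(theta = theta, residual = max(abs(r)), it = maxit, ok = max(abs(r)) < tol)
  }

  theta <- theta_init
  sol <- newton(theta, w_full)
  if (!sol$ok) {
    # continuation in g from the intrinsic configuration
    theta <- theta0 + cumsum(c(0, h * kbar))
    for (f in seq(0.1, 1, by = 0.1)) {
      sol <- newton(theta, node_weights(s, profiles, layout, g * f))
      theta <- sol$theta
    }
    if (!sol$ok)
      stop(sprintf("equilibrium solver failed to converge (residual %.3e)",
                   sol$residual), call. = FALSE)
  }
  list(theta = sol$theta, residual = sol$residual, iterations = sol$it,
       weights = w_full)
}

# Nodal recovery of the current curvature theta'(s) from the moment balance:
# B (theta' - kappa) = integral_s^ell w sin(theta) dsigma (zero at the tip),
# so theta' = kappa exactly when the load vanishes.  Used for the
# proprioceptive and secondary-growth terms of the sensing equation.
recover_dtheta <- function(s, theta, kappa, profiles, weights) {
  n <- length(s)
  ell <- s[n]
  h <- diff(s)
  f <- weights * sin(theta)
  seg <- h * (f[-n] + f[-1]) / 2
  Mom <- rev(cumsum(rev(c(seg, 0))))
  Bx <- profile_B(profiles, pmax(ell - s, 0))
  kappa + Mom / Bx
}

#' Reconstruct the planar centerline from the inclination field
#'
#' Integrates the unit tangent `(sin theta, cos theta)` from the clamped base
#' (placed at the origin) by the trapezoid rule on the nodal mesh.
#'
#' @param theta nodal inclination from the vertical, rad.
#' @param s nodal arc lengths, m.
#' @return An object of class `centerline`: a data frame with columns
#'   `s`, `x`, `y`.
#' @export
reconstruct_centerline <- function(theta, s) {
  stopifnot(length(theta) == length(s))
  h <- diff(s)
  tx <- sin(theta); ty <- cos(theta)
  x <- cumsum(c(0, h * (tx[-length(tx)] + tx[-1]) / 2))
  y <- cumsum(c(0, h * (ty[-length(ty)] + ty[-1]) / 2))
  structure(data.frame(s = s, x = x, y = y),
            class = c("centerline", "data.frame"))
}

#' Reach and orientation of a centerline
#'
#' Reach is the straight-line distance from base to apex; orientation is the
#' slope angle of that line above the horizontal, from the two-argument
#' arctangent of the tip coordinates. Reach never exceeds the arc length.
#'
#' @param centerline a [reconstruct_centerline] result (or any data frame with
#'   columns `x`, `y` whose last row is the tip).
#' @return Named numeric vector `c(reach = , orientation = )` (m, rad).
#' @export
reach_orientation <- function(centerline) {
  n <- nrow(centerline)
  xf <- centerline$x[n]; yf <- centerline$y[n]
  r <- sqrt(xf^2 + yf^2)
  if (r == 0) stop("zero-length rod: reach undefined", call. = FALSE)
  c(reach = r, orientation = atan2(yf, xf))
}
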