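# Shared fixtures and independent oracles, built in code.

# uniform rod: linear density 1 kg/m (rho3 = 1/pi, R = 1), rigidity B = 1
# (sigmoid with zero slope is the constant a/2), no leaves
uniform_profiles <- function(density = 1, B = 1) {
  material_profiles(quad_rho3 = c(0, 0, density / pi),
                    quad_R    = c(0, 0, 1),
                    quad_vR   = c(0, 0, 0),
                    sig_B     = c(2 * B, 0, 0.5),
                    sig_ml    = c(0, 1, 0))
}

no_leaves <- leaf_layout(0, 0)

# profiles with zero mass everywhere but otherwise species-like, for the
# weightless-equivalence experiments
massless_profiles <- function(profiles) {
  profiles$quad_rho3 <- c(0, 0, 0)
  profiles$sig_ml <- c(0, 1, 0)
  profiles
}

# Independent shooting oracle for the cantilever equilibrium:
# theta'' = -(w(s)/B) sin(theta), theta(0) = theta0, theta'(ell) = 0,
# with w the hanging weight per unit length of a uniform rod, w(s) = q (ell-s).
shoot_cantilever <- function(theta0, q = 1, B = 1, ell = 1) {
  f <- function(s, y, p) list(c(y[2], -(q * (ell - s) / B) * sin(y[1])))
  tip_slope <- function(c0) {
    o <- deSolve::ode(c(theta0, c0), c(0, ell), f, NULL,
                      rtol = 1e-12, atol = 1e-12)
    o[nrow(o), 3]
  }
  c0 <- stats::uniroot(tip_slope, c(-2, 2), tol = 1e-12)$root
  o <- deSolve::ode(c(theta0, c0), seq(0, ell, length.out = 401), f, NULL,
                    rtol = 1e-12, atol = 1e-12)
  list(s = o[, 1], theta = o[, 2])
}

# Independent fixed-step RK4 method-of-lines integrator for the sine-law
# system (same clamp convention as simulate_sine_law)
rk4_sine_law <- function(beta, gamma, n, n_steps, S_len = 1, T_len = 2,
                         theta0 = 0, kappa0 = 1) {
  s <- seq(0, S_len, length.out = n + 1L)
  h <- diff(s)
  k <- rep_len(kappa0, n + 1L)
  dt <- T_len / n_steps
  theta_of <- function(k) theta0 + cumsum(c(0, h * (k[-length(k)] + k[-1]) / 2))
  f <- function(k) -beta * sin(theta_of(k)) - gamma * k
  for (i in seq_len(n_steps)) {
    k1 <- f(k); k2 <- f(k + dt / 2 * k1)
    k3 <- f(k + dt / 2 * k2); k4 <- f(k + dt * k3)
    k <- k + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  list(s = s, theta = theta_of(k), kappa = k)
}

# default leafy layout used for species-like simulations: two opposite leaves
# every 5 cm along the initial shoot
default_layout <- leaf_layout(seq(0, 0.25, by = 0.05), rep(2L, 6))
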