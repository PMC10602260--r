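# Evolution of the intrinsic curvature and orchestration of the coupled model.
#
# Sensing equation (full model):
#   dt kappa = G (vR/R^2) (alpha cos theta - beta sin theta)
#              - G gamma theta' - delta (dtB/B) (kappa - theta')
# Weightless reduced model:
#   dt kappa = G (vR/R^2) (alpha cos theta - beta sin theta) - G gamma kappa
#
# Per time step: (i) advance the extension map (exact characteristics),
# (ii) refine the mesh where growth stretched it, (iii) semi-implicit backward
# Euler update of kappa (theta-dependent terms frozen at the previous
# equilibrium; the delta-relaxation treated implicitly), (iv) full model only:
# re-solve the static balance for theta; weightless model: integrate
# theta' = kappa from the clamp.

#' Sensing parameters
#'
#' `alpha` and `beta` scale the response to a directed stimulus (day), `gamma`
#' the proprioceptive straightening (dimensionless), `delta` the coupling of
#' secondary-growth rigidification into the intrinsic curvature
#' (dimensionless, non-negative).
#'
#' @param alpha,beta directed-stimulus gains, day.
#' @param gamma proprioceptive gain; negative values are admitted only for
#'   stability experiments.
#' @param delta radial-expansion ("negative proprioception") intensity, >= 0.
#' @return An object of class `sensing_params`.
#' @export
sensing_params <- function(alpha, beta, gamma, delta = 0) {
  if (delta < 0) stop("delta must be non-negative", call. = FALSE)
  structure(list(alpha = alpha, beta = beta, gamma = gamma, delta = delta),
            class = "sensing_params")
}

#' Polar reparametrization of the stimulus pair
#'
#' Writes `alpha cos(theta) - beta sin(theta)` as
#' `beta_tilde * sin(theta_p - theta)` with `beta_tilde = sqrt(alpha^2 + beta^2)`
#' and `theta_p` the two-argument arctangent chosen so that
#' `alpha = beta_tilde sin(theta_p)` and `beta = beta_tilde cos(theta_p)` hold
#' exactly. `theta_p` is the inclination (from the vertical) towards which the
#' stimulus steers the shoot.
#'
#' @param params a [sensing_params] object.
#' @return List with `beta_tilde` (day) and `theta_p` (rad; `NA` with a
#'   `defined = FALSE` flag when `alpha = beta = 0`).
#' @export
polar_reparam <- function(params) {
  bt <- sqrt(params$alpha^2 + params$beta^2)
  if (bt == 0)
    return(list(beta_tilde = 0, theta_p = NA_real_, defined = FALSE))
  list(beta_tilde = bt, theta_p = atan2(params$alpha, params$beta),
       defined = TRUE)
}

#' Relative rigidification rate dtB/B
#'
#' As the shoot extends, a material point recedes from the tip at the rate
#' `ell_dot - ds/dt`, so its rigidity drifts at
#' `dtB/B = B'(x) (ell_dot - ds/dt) / B(x)` with `x = ell - s`. Sub-apical
#' points give `B'(x) G0 lg / B(x)`; the tip itself travels with the tip and
#' gives 0. Non-negative whenever `B` increases away from the tip.
#'
#' @param profiles a [material_profiles].
#' @param map an [arclength_map].
#' @param params a [growth_params].
#' @param s arc length(s), m, within `[0, ell(t)]`.
#' @return Relative rigidification rate, day^-1.
#' @export
dtB_over_B <- function(profiles, map, params, s) {
  ell <- map_length(map)
  if (any(s > ell + 1e-12 * max(1, ell)))
    stop("s must not exceed ell(t)", call. = FALSE)
  x <- pmax(ell - s, 0)
  vmat <- material_velocity(map, params, s)
  profile_B_prime(profiles, x) * (extension_rate(params) - vmat) / profile_B(profiles, x)
}

#' Intrinsic curvature rate of the sensing equation
#'
#' Pointwise right-hand side of the curvature evolution law: directed stimulus
#' weighted by `G vR / R^2`, proprioceptive straightening `-G gamma theta'`,
#' and the secondary-growth relaxation `-delta (dtB/B) (kappa - theta')`.
#'
#' @param theta inclination, rad.
#' @param dtheta current-configuration curvature `theta'`, m^-1.
#' @param kappa intrinsic curvature, m^-1.
#' @param G local extension factor at the point, day^-1.
#' @param vR radial expansion rate at the point, m day^-1.
#' @param R cross-section radius at the point, m (positive).
#' @param dtBB relative rigidification rate at the point, day^-1.
#' @param sensing a [sensing_params].
#' @return Curvature rate, m^-1 day^-1 (vectorised).
#' @export
curvature_rate <- function(theta, dtheta, kappa, G, vR, R, dtBB, sensing) {
  if (any(R <= 0)) stop("cross-section radius must be positive", call. = FALSE)
  G * (vR / R^2) * (sensing$alpha * cos(theta) - sensing$beta * sin(theta)) -
    G * sensing$gamma * dtheta -
    sensing$delta * dtBB * (kappa - dtheta)
}

#' Simulate the growing searcher shoot
#'
#' Time-integrates the coupled system: tip extension, intrinsic-curvature
#' evolution under sensing, and (full model) the static balance of the heavy
#' rod, or (weightless model) the purely intrinsic configuration
#' `theta' = kappa`. Initial intrinsic curvature is zero; the initial
#' inclination solves the static balance (full) or is the constant clamp angle
#' (weightless). New tip material inherits the tip condition
#' `kappa(ell) = theta'(ell)`.
#'
#' @param profiles a [material_profiles].
#' @param growth a [growth_params].
#' @param sensing a [sensing_params].
#' @param theta0 clamp angle from the vertical, rad.
#' @param T_final final time, day.
#' @param dt time step of the sensing/statics splitting, day.
#' @param model `"full"` (with gravity) or `"weightless"`.
#' @param layout a [leaf_layout] of lumped leaf masses (full model only).
#' @param g gravitational acceleration, m s^-2.
#' @param ds target spatial resolution of the mesh, m.
#' @param n_out number of output frames (evenly spaced in time, including the
#'   initial and final states).
#' @return An object of class `shoot_trajectory`: list with `frames` (a list
#'   of data frames `t, S, s, x, theta, kappa, px, py`), `summary` (data frame
#'   `t, ell, reach, orientation, tip_theta`), and the call parameters.
#' @export
simulate_shoot <- function(profiles, growth, sensing, theta0,
                           T_final, dt = 0.01,
                           model = c("full", "weightless"),
                           layout = leaf_layout(0, 0), g = 9.81,
                           ds = 0.005, n_out = 11L) {
  model <- match.arg(model)
  stopifnot(T_final > 0, dt > 0)
  n0 <- max(16L, ceiling(growth$ell0 / ds))
  map <- arclength_map(growth, n0)
  kappa <- numeric(length(map$s))

  if (model == "full") {
    eq <- solve_equilibrium(map$s, kappa, theta0, profiles, layout, g = g)
    theta <- eq$theta
    weights <- eq$weights
  } else {
    theta <- rep(theta0, length(map$s))
    weights <- numeric(length(map$s))
  }

  nsteps <- ceiling(T_final / dt - 1e-9)
  out_times <- seq(0, nsteps) * dt
  rec_at <- unique(round(seq(0, nsteps, length.out = n_out)))

  frames <- list()
  summ <- list()
  record <- function(step) {
    cl <- reconstruct_centerline(theta, map$s)
    ro <- reach_orientation(cl)
    frames[[length(frames) + 1L]] <<- data.frame(
      t = map$t, S = map$S, s = map$s, x = map_length(map) - map$s,
      theta = theta, kappa = kappa, px = cl$x, py = cl$y)
    summ[[length(summ) + 1L]] <<- data.frame(
      t = map$t, ell = map_length(map), reach = ro[["reach"]],
      orientation = ro[["orientation"]], tip_theta = theta[length(theta)])
  }
  if (0 %in% rec_at) record(0L)

  for (step in seq_len(nsteps)) {
    map <- advance_extension(map, growth, dt)
    ref <- refine_map(map, list(theta = theta, kappa = kappa))
    map <- ref$map
    theta <- ref$fields$theta
    kappa <- ref$fields$kappa
    s <- map$s
    ell <- map_length(map)
    x <- pmax(ell - s, 0)

    if (model == "full") {
      weights <- node_weights(s, profiles, layout, g)
      dtheta <- recover_dtheta(s, theta, kappa, profiles, weights)
    } else {
      dtheta <- kappa
    }
    # tip condition: newly stretched tip material carries the
    # moment-free curvature
    kappa[length(kappa)] <- dtheta[length(dtheta)]

    G <- growth_field(map, growth, s)
    R <- profile_radius(profiles, x)
    if (any(R[G > 0] <= 0))
      stop("radius profile vanished inside the extension zone", call. = FALSE)
    vR <- profile_vR(profiles, x)
    stim <- ifelse(G > 0, G * (vR / pmax(R, .Machine$double.eps)^2) *
                     (sensing$alpha * cos(theta) - sensing$beta * sin(theta)), 0)

    if (model == "full") {
      dtBB <- dtB_over_B(profiles, map, growth, s)
      kappa <- (kappa + dt * (stim - G * sensing$gamma * dtheta +
                                sensing$delta * dtBB * dtheta)) /
               (1 + dt * sensing$delta * dtBB)
      eq <- solve_equilibrium(s, kappa, theta0, profiles, layout, g = g,
                              theta_init = theta)
      theta <- eq$theta
      weights <- eq$weights
    } else {
      # same splitting as the full model with theta' = kappa, so that the
      # two models coincide exactly when the full model carries no weight
      kappa <- kappa + dt * (stim - G * sensing$gamma * kappa)
      h <- diff(s)
      theta <- theta0 + cumsum(c(0, h * (kappa[-length(kappa)] + kappa[-1]) / 2))
    }
    if (step %in% rec_at) record(step)
  }

  structure(list(frames = frames, summary = do.call(rbind, summ),
                 model = model, growth = growth, sensing = sensing,
                 theta0 = theta0, dt = dt, g = g),
            class = "shoot_trajectory")
}

#' @export
print.shoot_trajectory <- function(x, ...) {
  n <- nrow(x$summary)
  cat(sprintf("Shoot trajectory (%s model): %d frames, t in [%g, %g] day\n",
              x$model, n, x$summary$t[1], x$summary$t[n]))
  cat(sprintf("  final length %.3f m, reach %.3f m, orientation %.1f deg from horizontal\n",
              x$summary$ell[n], x$summary$reach[n],
              x$summary$orientation[n] * 180 / pi))
  invisible(x)
}

#' Build a reach/orientation runner for calibration
#'
#' Returns a function `(alpha, beta, gamma) -> c(reach, orientation)` that
#' re-simulates the shoot with those sensing gains and reports the final reach
#' and orientation, as consumed by [estimate_sensing()].
#'
#' @inheritParams simulate_shoot
#' @param delta fixed radial-expansion intensity used by every run.
#' @return A function of `(alpha, beta, gamma)`.
#' @export
make_shoot_runner <- function(profiles, growth, theta0, T_final, dt = 0.05,
                              model = c("weightless", "full"),
                              layout = leaf_layout(0, 0), delta = 0,
                              g = 9.81, ds = 0.005) {
  model <- match.arg(model)
  function(alpha, beta, gamma) {
    tr <- simulate_shoot(profiles, growth,
                         sensing_params(alpha, beta, gamma, delta),
                         theta0, T_final, dt, model = model,
                         layout = layout, g = g, ds = ds, n_out = 2L)
    n <- nrow(tr$summary)
    c(reach = tr$summary$reach[n], orientation = tr$summary$orientation[n])
  }
}
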