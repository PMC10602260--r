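test_that("polar reparametrization inverts exactly", {
  expect_equal(polar_reparam(sensing_params(0, 1, 0))[c("beta_tilde", "theta_p")],
               list(beta_tilde = 1, theta_p = 0))
  expect_equal(polar_reparam(sensing_params(1, 0, 0))[c("beta_tilde", "theta_p")],
               list(beta_tilde = 1, theta_p = pi / 2))
  p <- polar_reparam(sensing_params(5e-4, -5e-3, 0))
  expect_equal(p$beta_tilde, sqrt(5e-4^2 + 5e-3^2), tolerance = 1e-12)
  expect_equal(p$beta_tilde * sin(p$theta_p), 5e-4, tolerance = 1e-12)
  expect_equal(p$beta_tilde * cos(p$theta_p), -5e-3, tolerance = 1e-12)
  z <- polar_reparam(sensing_params(0, 0, 0))
  expect_false(z$defined)
  expect_equal(z$beta_tilde, 0)
})

test_that("rigidification drift dtB/B is zero without growth and at the tip", {
  cal <- species_calibration("C_guianense")
  m <- arclength_map(cal$growth, 60)
  gp0 <- growth_params(0, cal$growth$lg, cal$growth$ell0)
  expect_equal(dtB_over_B(cal$profiles, m, gp0, m$s), rep(0, length(m$s)))
  v <- dtB_over_B(cal$profiles, m, cal$growth, m$s)
  expect_equal(v[length(v)], 0)              # the tip recedes from itself at rate 0
  expect_true(all(v >= 0))                   # B increasing away from the tip
})

test_that("dtB/B matches a finite-difference oracle at sub-apical points", {
  cal <- species_calibration("C_guianense")
  m <- arclength_map(cal$growth, 60)
  s0 <- 0.05                                 # well below the extension zone
  got <- dtB_over_B(cal$profiles, m, cal$growth, s0)
  # material point is stationary, so x(t) = ell(t) - s0 grows at ell_dot;
  # d/dt log B = (log B(x + ell_dot dt) - log B(x - ell_dot dt)) / (2 dt)
  ld <- extension_rate(cal$growth)
  x <- map_length(m) - s0
  dt <- 1e-4
  oracle <- (log(profile_B(cal$profiles, x + ld * dt)) -
             log(profile_B(cal$profiles, x - ld * dt))) / (2 * dt)
  expect_equal(got, oracle, tolerance = 1e-6)
})

test_that("curvature rate vanishes in the documented degenerate cases", {
  z <- sensing_params(0, 0, 0, 0)
  expect_equal(curvature_rate(0.5, 0.2, 0.1, G = 0.1, vR = 1e-5, R = 1e-3,
                              dtBB = 0.1, z), 0)
  # at theta = theta_p the directed stimulus vanishes
  sp <- sensing_params(3e-4, -2e-3, 0, 0)
  thp <- polar_reparam(sp)$theta_p
  expect_equal(curvature_rate(thp, 0.2, 0.1, G = 0.1, vR = 1e-5, R = 1e-3,
                              dtBB = 0.1, sp), 0, tolerance = 1e-12)
  # outside the growth zone with delta = 0 nothing drives the curvature
  sp2 <- sensing_params(1e-3, 1e-3, 1e-2, 0)
  expect_equal(curvature_rate(0.5, 0.2, 0.1, G = 0, vR = 1e-5, R = 1e-3,
                              dtBB = 0.1, sp2), 0)
  expect_error(curvature_rate(0.5, 0.2, 0.1, 0.1, 1e-5, R = 0, 0.1, z),
               "positive")
})

test_that("zero sensing and zero gravity keep the elongating rod straight", {
  pr <- massless_profiles(species_calibration("C_guianense")$profiles)
  gp <- growth_params(0.12, 0.17, 0.3)
  tr <- simulate_shoot(pr, gp, sensing_params(0, 0, 0), theta0 = 0.6,
                       T_final = 5, dt = 0.1, model = "full", n_out = 3)
  last <- tr$frames[[length(tr$frames)]]
  expect_equal(last$theta, rep(0.6, nrow(last)), tolerance = 1e-9)
  expect_equal(tr$summary$reach[3], tr$summary$ell[3], tolerance = 1e-9)
})

test_that("massless full model coincides with the weightless model", {
  cal <- species_calibration("T_jasminoides")
  pr0 <- massless_profiles(cal$profiles)
  trF <- simulate_shoot(pr0, cal$growth, cal$sensing, cal$theta0,
                        T_final = 8, dt = 0.05, model = "full", n_out = 3)
  trW <- simulate_shoot(pr0, cal$growth, cal$sensing, cal$theta0,
                        T_final = 8, dt = 0.05, model = "weightless", n_out = 3)
  nf <- length(trF$frames)
  expect_equal(trF$frames[[nf]]$theta, trW$frames[[nf]]$theta, tolerance = 1e-8)
  expect_equal(trF$frames[[nf]]$kappa, trW$frames[[nf]]$kappa, tolerance = 1e-8)
})

test_that("trajectories self-converge at first order in dt", {
  cal <- species_calibration("C_guianense")
  tip <- function(dt) {
    tr <- simulate_shoot(cal$profiles, cal$growth, cal$sensing, cal$theta0,
                         T_final = 6, dt = dt, model = "full",
                         layout = default_layout, n_out = 2L)
    tr$summary$tip_theta[2]
  }
  ref <- tip(0.0125)
  errs <- abs(sapply(c(0.4, 0.2, 0.1), tip) - ref)
  expect_true(all(diff(errs) < 0))
  expect_gt(errs[1] / errs[3], 2.5)          # order >= 1 over a 4x refinement
})

test_that("reach never exceeds the current length in any output frame", {
  cal <- species_calibration("C_guianense")
  tr <- simulate_shoot(cal$profiles, cal$growth, cal$sensing, cal$theta0,
                       T_final = 15, dt = 0.1, model = "full",
                       layout = default_layout, n_out = 6L)
  expect_true(all(tr$summary$reach <= tr$summary$ell + 1e-12))
})

test_that("the delta term opposes proprioception when rigidity grows", {
  cal <- species_calibration("C_guianense")
  m <- arclength_map(cal$growth, 60)
  s <- 0.1
  dtBB <- dtB_over_B(cal$profiles, m, cal$growth, s)
  expect_gt(dtBB, 0)
  theta <- 0.4; dth <- 0.5; kap <- 0.2
  base <- sensing_params(0, 0, 1e-2, 0)
  with_d <- sensing_params(0, 0, 1e-2, 0.5)
  prop_term <- curvature_rate(theta, dth, kap, G = 0.1, vR = 1e-5, R = 1e-3,
                              dtBB = dtBB, base)
  delta_term <- curvature_rate(theta, dth, kap, G = 0, vR = 1e-5, R = 1e-3,
                               dtBB = dtBB, with_d)
  # proprioception pulls kappa-rate down (dth > 0); the delta term pushes it
  # up whenever kappa < dth
  expect_lt(prop_term, 0)
  expect_gt(delta_term, 0)
})
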