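make_sample <- function(n = 10, L = 1, profiles = NULL, ext = NULL) {
  if (is.null(profiles)) profiles <- species_calibration("C_guianense")$profiles
  len <- rep(L / n, n)
  s <- cumsum(c(0, len))[1:n]
  x <- L - s
  R <- profile_radius(profiles, x)
  morphology_sample(
    data.frame(index = 1:n, length_m = len, diameter_m = 2 * R,
               leaf_count = 2L,
               mass_kg = profile_rho3(profiles, x) * pi * R^2 * len,
               leaf_mass_kg = profile_ml(profiles, x)),
    reach_m = 0.8 * L, orientation_rad = 0.2,
    stiffness = data.frame(x_m = x, EI_Nm2 = profile_B(profiles, x)))
}

test_that("radial expansion rate follows the internode finite difference", {
  ms <- morphology_sample(
    data.frame(index = 1:2, length_m = c(0.1, 0.1),
               diameter_m = c(2e-3, 1.6e-3), leaf_count = 0L),
    reach_m = 0.1, orientation_rad = 0)
  v <- estimate_vR(ms, ext_rate = 0.02)
  expect_equal(v$dt_day, 5)
  expect_equal(v$vR, 4e-5)
  # equal radii give zero rate; reversing the order flips the sign
  ms2 <- ms; ms2$internodes$diameter_m <- c(2e-3, 2e-3)
  expect_equal(estimate_vR(ms2, 0.02)$vR, 0)
  ms3 <- ms; ms3$internodes$diameter_m <- rev(ms$internodes$diameter_m)
  expect_equal(estimate_vR(ms3, 0.02)$vR, -v$vR)
  expect_error(estimate_vR(ms, 0), "positive")
})

test_that("noise-free profiles are recovered exactly by the fits", {
  truth <- species_calibration("C_guianense")$profiles
  # self-consistent expansion rate: vR(x) = ell_dot * R'(x)
  ld <- 0.0204
  truth$quad_vR <- c(0, 2 * ld * truth$quad_R[1], ld * truth$quad_R[2])
  ms <- make_sample(12, 1, truth)
  fit <- fit_profiles(ms, ext_rate = ld)
  expect_equal(fit$profiles$quad_R, truth$quad_R, tolerance = 1e-8)
  expect_equal(fit$profiles$quad_rho3, truth$quad_rho3, tolerance = 1e-8)
  expect_equal(fit$profiles$quad_vR, truth$quad_vR, tolerance = 1e-8)
  expect_equal(fit$profiles$sig_B, truth$sig_B, tolerance = 1e-6)
  expect_equal(fit$profiles$sig_ml, truth$sig_ml, tolerance = 1e-6)
  r2 <- fit$report$value[fit$report$index == "R2"]
  expect_true(all(abs(r2 - 1) < 1e-10))
  expect_true(all(fit$report$value[fit$report$index == "RMSD"] < 1e-10))
})

test_that("noisy fits recover the radius profile within sampling error", {
  truth <- species_calibration("C_guianense")$profiles
  set.seed(11)
  n <- 30
  x <- seq(0, 1.2, length.out = n)
  hits <- 0L
  for (rep in 1:20) {
    y <- profile_radius(truth, x) * exp(rnorm(n, 0, 0.05))
    fit <- lm(y ~ I(x^2) + x)
    se <- sqrt(diag(vcov(fit)))[c("I(x^2)", "x", "(Intercept)")]
    est <- coef(fit)[c("I(x^2)", "x", "(Intercept)")]
    if (all(abs(est - truth$quad_R) <= 3 * se)) hits <- hits + 1L
  }
  expect_gte(hits, 17L)                      # ~ 3-sigma coverage
})

test_that("growth estimation reproduces the worked pooling example", {
  # totals 0.50/0.56/0.62 m at days 0/3/6 with an extending zone of 0.15 m
  lengths <- rbind(c(0.175, 0.175, 0.175),
                   c(0.175, 0.175, 0.175),
                   c(0.075, 0.105, 0.135),
                   c(0.075, 0.105, 0.135))
  es <- extension_series(c(0, 3, 6), lengths, "example")
  expect_equal(es$totals, c(0.50, 0.56, 0.62))
  g <- estimate_growth(es)
  expect_equal(g$ell_dot, 0.02, tolerance = 1e-12)
  expect_equal(g$lg, 0.15, tolerance = 1e-12)
  expect_equal(g$G0, 0.02 / 0.15, tolerance = 1e-12)
})

test_that("growth estimation discards shoots with elongating basal internodes", {
  growing_base <- extension_series(
    c(0, 3), rbind(c(0.2, 0.25), c(0.1, 0.15)), "bad")
  ok <- extension_series(
    c(0, 3), rbind(c(0.2, 0.2), c(0.1, 0.16)), "good")
  g <- estimate_growth(list(growing_base, ok))
  expect_equal(g$n_used, 1L)
  expect_equal(g$n_discarded, 1L)
  expect_equal(g$lg, 0.1)
  expect_error(estimate_growth(growing_base), "discarded")
})

test_that("no growth between dates gives a zero extension rate", {
  es <- extension_series(c(0, 3), rbind(c(0.2, 0.2), c(0.1, 0.1)), "flat")
  expect_error(estimate_growth(es), "extending")   # nothing extends either
  # a shoot with static base and one extending internode but equal totals
  # cannot occur; zero rate is exercised via near-zero growth
  es2 <- extension_series(c(0, 3), rbind(c(0.2, 0.2), c(0.1, 0.102)), "slow")
  g <- estimate_growth(es2, threshold = 0.01)
  expect_equal(g$ell_dot, 0.002 / 3, tolerance = 1e-12)
})

test_that("the reach/orientation objective is a symmetric sum of squares", {
  expect_equal(objective_F(c(1, 0.5), c(1, 0.5)), 0)
  expect_equal(objective_F(c(1, 0.5), c(0.8, 0.3)), 0.08, tolerance = 1e-12)
  expect_equal(objective_F(c(0.8, 0.3), c(1, 0.5)),
               objective_F(c(1, 0.5), c(0.8, 0.3)))
  expect_equal(objective_F(c(1, 0.5), c(0.8, 0.3), scale = c(2, 0)),
               0.08, tolerance = 1e-12)
})

test_that("sensing estimation returns the guess when the target sits on it", {
  runner <- function(alpha, beta, gamma) c(alpha, beta)   # transparent model
  est <- estimate_sensing(runner, reach_e = 2e-3, orient_e = -1e-3,
                          guess = c(2e-3, -1e-3), gamma_grid = 0.01)
  expect_equal(est$gamma, 0.01)
  expect_lt(est$F, 1e-16)
  expect_equal(est$alpha, 2e-3, tolerance = 1e-6)
  expect_equal(est$beta, -1e-3, tolerance = 1e-6)
})

test_that("bending stiffness follows the elliptic second moment of area", {
  b <- bending_stiffness(7.5e-4, 2e-3, 2e-3)
  expect_equal(b$I, pi * (2e-3)^4 / 64, tolerance = 1e-12)
  expect_equal(b$E_str, 7.5e-4 / (pi * (2e-3)^4 / 64), tolerance = 1e-9)
  b2 <- bending_stiffness(7.5e-4, 4e-3, 4e-3)
  expect_equal(b2$I / b$I, 16, tolerance = 1e-12)
  expect_equal(b$E_str / b2$E_str, 16, tolerance = 1e-12)
  expect_error(bending_stiffness(1, -1e-3, 1e-3), "positive")
})

test_that("four-point EI inverts the standard deflection formula", {
  EI <- 7.5e-4; L <- 0.15; l <- 0.09; a <- (L - l) / 2
  F <- c(0.05, 0.1, 0.15, 0.2)
  defl <- F * a * (3 * L^2 - 4 * a^2) / (24 * EI)
  expect_equal(four_point_EI(F, defl, L, l), EI, tolerance = 1e-10)
})
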