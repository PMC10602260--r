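cg_spec <- function(noise = 0, seed = 1L, ...) {
  cal <- species_calibration("C_guianense")
  # grow the sampled shoot to ~0.7 m so the rigidity sigmoid's rise is
  # actually observed and its three coefficients are identifiable
  synthesis_spec(cal$profiles, cal$growth, cal$sensing, cal$theta0,
                 n_internodes = 14L, noise_sd = noise, seed = seed,
                 T_final = 20, dt = 0.1, ...)
}

test_that("zero-noise morphology reproduces the truth profiles at the stations", {
  ms <- generate_morphology(cg_spec())
  truth <- attr(ms, "truth")$profiles
  st <- morphorod:::sample_stations(ms)
  expect_equal(ms$internodes$diameter_m, 2 * profile_radius(truth, st$x),
               tolerance = 1e-12)
  expect_equal(ms$internodes$leaf_mass_kg, profile_ml(truth, st$x),
               tolerance = 1e-12)
})

test_that("generation is deterministic in the seed", {
  a <- generate_morphology(cg_spec(noise = 0.05, seed = 3))
  b <- generate_morphology(cg_spec(noise = 0.05, seed = 3))
  cc <- generate_morphology(cg_spec(noise = 0.05, seed = 4))
  expect_identical(a$internodes, b$internodes)
  expect_false(identical(a$internodes$diameter_m, cc$internodes$diameter_m))
  ea <- generate_extension_series(cg_spec(noise = 0.05, seed = 3))
  eb <- generate_extension_series(cg_spec(noise = 0.05, seed = 3))
  expect_identical(ea$lengths, eb$lengths)
})

test_that("fit_profiles round-trips the zero-noise generator output", {
  ms <- generate_morphology(cg_spec())
  truth <- attr(ms, "truth")
  fit <- fit_profiles(ms, ext_rate = extension_rate(truth$growth))
  expect_equal(fit$profiles$quad_R, truth$profiles$quad_R, tolerance = 1e-8)
  expect_equal(fit$profiles$quad_rho3, truth$profiles$quad_rho3, tolerance = 1e-8)
  expect_equal(fit$profiles$quad_vR, truth$profiles$quad_vR, tolerance = 1e-8)
  expect_equal(fit$profiles$sig_B, truth$profiles$sig_B, tolerance = 1e-6)
  expect_equal(fit$profiles$sig_ml, truth$profiles$sig_ml, tolerance = 1e-6)
})

test_that("extension series: totals are column sums and zero G0 freezes them", {
  es <- generate_extension_series(cg_spec())
  expect_equal(es$totals, colSums(es$lengths))
  cal <- species_calibration("C_guianense")
  sp0 <- synthesis_spec(cal$profiles,
                        growth_params(0, cal$growth$lg, cal$growth$ell0),
                        cal$sensing, cal$theta0, T_final = 10, dt = 0.1)
  es0 <- generate_extension_series(sp0)
  expect_true(all(es0$lengths == es0$lengths[, 1]))
})

test_that("estimate_growth recovers G0 from noise-free series within 2%", {
  series <- lapply(1:5, function(i) generate_extension_series(cg_spec(seed = i)))
  g <- estimate_growth(series)
  expect_lt(abs(g$G0 - 0.12) / 0.12, 0.02)
  expect_equal(g$lg, 0.17, tolerance = 1e-10)
  expect_equal(g$ell_dot, 0.12 * 0.17, tolerance = 1e-10)
})

test_that("noisy lengths remain positive and non-decreasing in time", {
  es <- generate_extension_series(cg_spec(noise = 0.08, seed = 9))
  expect_true(all(es$lengths > 0))
  expect_true(all(apply(es$lengths, 1, function(r) all(diff(r) >= 0))))
})
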