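# Synthetic field data with known ground truth, emulating the two table kinds
# consumed by the calibration pipeline: per-internode morphology (lengths,
# diameters, masses, leaf data, shoot reach/orientation, stiffness
# observations) and dated extension series.  Every calibration stage can thus
# be exercised round-trip without field measurements.

#' Specification of a synthetic shoot data set
#'
#' Ground truth plus observation design. Noise is multiplicative log-normal
#' on positive observables (preserves positivity); a fixed seed makes the
#' output reproducible.
#'
#' @param profiles truth [material_profiles]. The radial expansion rate is
#'   not a free truth: consistency of the distance-from-tip maturation
#'   assumption forces `vR(x) = ell_dot * R'(x)`, and the generator derives it
#'   from the radius profile and the growth parameters (the stored `quad_vR`
#'   is overridden).
#' @param growth truth [growth_params].
#' @param sensing truth [sensing_params].
#' @param theta0 truth clamp angle, rad.
#' @param n_internodes number of internodes of the morphology sample (>= 3).
#' @param shoot_length total length of the measured shoot, m; defaults to the
#'   length the truth simulation reaches, `ell0 + G0 lg T_final`, so that the
#'   morphology table and the reach/orientation describe the same shoot.
#' @param leaf_count leaves borne at each internode base (default 2, the
#'   opposite phyllotaxy typical of the study group).
#' @param noise_sd relative (log-scale) noise s.d. applied to lengths,
#'   diameters, masses and stiffness observations; 0 for exact data.
#' @param n_dates,date_spacing observation design of the extension series.
#' @param n_zone_internodes internodes spanning the extension zone at the
#'   first date (their lengths sum exactly to `lg`).
#' @param seed integer seed for the generator's RNG.
#' @param sim_model model used to compute the truth reach/orientation
#'   (`"weightless"` or `"full"`).
#' @param T_final,dt time horizon and step of the truth simulation.
#' @return An object of class `synthesis_spec`.
#' @export
synthesis_spec <- function(profiles, growth, sensing, theta0,
                           n_internodes = 12L, shoot_length = NULL,
                           leaf_count = 2L, noise_sd = 0,
                           n_dates = 3L, date_spacing = 3,
                           n_zone_internodes = 4L, seed = 1L,
                           sim_model = "weightless", T_final = 20, dt = 0.05) {
  stopifnot(n_internodes >= 3L, noise_sd >= 0, n_dates >= 2L)
  if (is.null(shoot_length))
    shoot_length <- growth$ell0 + extension_rate(growth) * T_final
  structure(list(profiles = profiles, growth = growth, sensing = sensing,
                 theta0 = theta0, n_internodes = as.integer(n_internodes),
                 shoot_length = shoot_length, leaf_count = as.integer(leaf_count),
                 noise_sd = noise_sd, n_dates = as.integer(n_dates),
                 date_spacing = date_spacing,
                 n_zone_internodes = as.integer(n_zone_internodes),
                 seed = as.integer(seed), sim_model = sim_model,
                 T_final = T_final, dt = dt),
            class = "synthesis_spec")
}

# truth vR(x) = ell_dot * R'(x), the rate at which a stationary material
# point's radius grows as its distance from the tip increases at ell_dot
derived_vR_coeffs <- function(profiles, growth) {
  ld <- extension_rate(growth)
  c(0, 2 * ld * profiles$quad_R[1], ld * profiles$quad_R[2])
}

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

lognoise <- function(x, sd) if (sd <= 0) x else x * exp(stats::rnorm(length(x), 0, sd))

#' Generate a synthetic morphology sample
#'
#' Internode bases are placed by cumulative lengths; diameters, segment
#' masses, single-leaf masses and stiffness observations are evaluated from
#' the truth profiles at the base stations (the same measurement model the
#' calibrator inverts); reach and orientation come from simulating the truth
#' parameters. Multiplicative noise is applied per the spec.
#'
#' @param spec a [synthesis_spec].
#' @return A [morphology_sample] with truth metadata in attribute `"truth"`.
#' @export
generate_morphology <- function(spec) {
  pr <- spec$profiles
  pr$quad_vR <- derived_vR_coeffs(pr, spec$growth)
  n <- spec$n_internodes
  len <- rep(spec$shoot_length / n, n)
  with_seed(spec$seed, {
    len <- lognoise(len, spec$noise_sd)
    L <- sum(len)
    s <- cumsum(c(0, len))[seq_len(n)]
    x <- L - s
    R <- profile_radius(pr, x)
    if (any(R <= 0) || any(profile_B(pr, x) <= 0))
      stop("truth profiles violate positivity over the sampled range", call. = FALSE)
    d <- lognoise(2 * R, spec$noise_sd)
    mass <- lognoise(profile_rho3(pr, x) * pi * R^2 * len, spec$noise_sd)
    lmass <- lognoise(profile_ml(pr, x), spec$noise_sd)
    stiff <- data.frame(x_m = x, EI_Nm2 = lognoise(profile_B(pr, x), spec$noise_sd))

    tr <- simulate_shoot(pr, spec$growth, spec$sensing, spec$theta0,
                         T_final = spec$T_final, dt = spec$dt,
                         model = spec$sim_model,
                         layout = leaf_layout(s, rep(spec$leaf_count, n)),
                         n_out = 2L)
    fin <- tr$summary[nrow(tr$summary), ]
    xb <- max(x)
    bend <- data.frame(EI_Nm2 = profile_B(pr, xb),
                       d_v_m = 2 * profile_radius(pr, xb),
                       d_h_m = 2 * profile_radius(pr, xb))
    sample <- morphology_sample(
      internodes = data.frame(index = seq_len(n), length_m = len,
                              diameter_m = d,
                              leaf_count = rep(spec$leaf_count, n),
                              mass_kg = mass, leaf_mass_kg = lmass),
      reach_m = min(fin$reach, sum(len)),   # reach <= arc length by construction

      orientation_rad = fin$orientation,
      bending = bend, stiffness = stiff)
    attr(sample, "truth") <- list(profiles = pr, growth = spec$growth,
                                  sensing = spec$sensing, theta0 = spec$theta0,
                                  reach = fin$reach, orientation = fin$orientation)
    sample
  })
}

#' Generate a synthetic extension time series
#'
#' The apical internodes spanning the extension zone (summed length exactly
#' `lg` at the first date) elongate proportionally so that the total length
#' grows at the analytic rate `G0 * lg`; basal internodes stay fixed; the
#' internode count is frozen over the (short) observation window. Totals are
#' always the column sums of the per-internode lengths.
#'
#' @param spec a [synthesis_spec].
#' @param shoot_id identifier stored in the series.
#' @return An [extension_series].
#' @export
generate_extension_series <- function(spec, shoot_id = "synthetic-1") {
  g <- spec$growth
  k <- spec$n_zone_internodes
  n <- spec$n_internodes
  stopifnot(k >= 1L, n > k)
  base_total <- g$ell0 - g$lg
  len0 <- c(rep(base_total / (n - k), n - k), rep(g$lg / k, k))
  dates <- seq(0, by = spec$date_spacing, length.out = spec$n_dates)
  zone <- seq(n - k + 1L, n)
  lengths <- sapply(dates, function(t) {
    l <- len0
    l[zone] <- len0[zone] * (1 + g$G0 * t)
    l
  })
  with_seed(spec$seed + 1L, {
    if (spec$noise_sd > 0)
      lengths <- apply(lengths, 2, lognoise, sd = spec$noise_sd)
    # measurement noise must not violate monotone growth of an internode
    lengths <- t(apply(lengths, 1, cummax))
    extension_series(dates, lengths, shoot_id)
  })
}
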