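# Data-to-parameters pipeline: profile fitting from internode morphology,
# radial-expansion-rate reconstruction, growth-parameter estimation from
# extension time series, sensing-parameter estimation by matching reach and
# orientation, and bending-derived stiffness.

#' Morphology sample of a searcher shoot
#'
#' One measured shoot: ordered internode records from the base, the
#' whole-shoot reach and orientation, and optionally a four-point-bending
#' record and direct stiffness/leaf-mass observations.
#'
#' Station convention: each internode's measurements (diameter, mass, single
#' leaf mass) are referred to the internode base at arc length
#' `s_i = sum of lengths below`, i.e. distance from tip `x_i = L - s_i` with
#' `L` the total measured length.
#'
#' @param internodes data frame with columns `index`, `length_m`,
#'   `diameter_m`, `leaf_count`, and optionally `mass_kg` and `leaf_mass_kg`.
#' @param reach_m measured reach, m.
#' @param orientation_rad measured orientation above the horizontal, rad.
#' @param bending optional data frame with columns `EI_Nm2`, `d_v_m`, `d_h_m`
#'   (one row per measurement position of the basal bending test).
#' @param stiffness optional data frame with columns `x_m`, `EI_Nm2`: direct
#'   flexural-rigidity observations along the shoot used for the `B(x)` fit;
#'   when absent, `B` observations are derived as `E_str * I(diameter)`.
#' @return An object of class `morphology_sample`.
#' @export
morphology_sample <- function(internodes, reach_m, orientation_rad,
                              bending = NULL, stiffness = NULL) {
  req <- c("index", "length_m", "diameter_m", "leaf_count")
  miss <- setdiff(req, names(internodes))
  if (length(miss))
    stop("internode table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (any(internodes$length_m <= 0)) stop("internode lengths must be positive", call. = FALSE)
  if (any(internodes$diameter_m <= 0)) stop("internode diameters must be positive", call. = FALSE)
  if (is.unsorted(internodes$index, strictly = TRUE))
    stop("internode indices must be strictly increasing from the base", call. = FALSE)
  if (reach_m > sum(internodes$length_m) + 1e-9)
    stop("reach cannot exceed the summed internode length", call. = FALSE)
  structure(list(internodes = internodes, reach_m = reach_m,
                 orientation_rad = orientation_rad, bending = bending,
                 stiffness = stiffness),
            class = "morphology_sample")
}

# Base arc lengths s_i and distances from tip x_i of a sample.
sample_stations <- function(sample) {
  len <- sample$internodes$length_m
  s <- cumsum(c(0, len))[seq_along(len)]
  L <- sum(len)
  list(s = s, x = L - s, L = L, len = len)
}

#' Extension time series of one shoot
#'
#' Per-internode lengths at successive observation dates.
#'
#' @param dates numeric vector of day offsets, strictly increasing.
#' @param lengths matrix of internode lengths (m), rows = internodes from the
#'   base, columns = dates; entries must be non-decreasing along each row.
#' @param shoot_id optional identifier.
#' @return An object of class `extension_series` with a `totals` field (total
#'   shoot length per date, the column sums).
#' @export
extension_series <- function(dates, lengths, shoot_id = NA_character_) {
  lengths <- as.matrix(lengths)
  if (any(diff(dates) <= 0)) stop("dates must be strictly increasing", call. = FALSE)
  if (ncol(lengths) != length(dates))
    stop("lengths must have one column per date", call. = FALSE)
  if (any(apply(lengths, 1, function(r) any(diff(r) < -1e-12))))
    stop("internode lengths must be non-decreasing in time", call. = FALSE)
  structure(list(dates = as.numeric(dates), lengths = lengths,
                 totals = colSums(lengths), shoot_id = shoot_id),
            class = "extension_series")
}

#' Radial expansion rate from internode radii
#'
#' Under the assumption that maturation depends only on the distance from the
#' tip, the radius at a station grows until it reaches the value one internode
#' below after the time `Delta_t_i = length_i / extension_rate` it takes the
#' tip to advance by one internode. The expansion rate at the base of
#' internode `i` is therefore `(R_i - R_{i+1}) / Delta_t_i`.
#'
#' Each estimate is attached to the midpoint of the spanned interval in
#' distance-from-tip (`x_mid`), where a finite difference of a smooth radius
#' profile is exact to second order.
#'
#' @param sample a [morphology_sample].
#' @param ext_rate tip extension rate, m day^-1 (positive).
#' @return Data frame with columns `s`, `x`, `x_mid`, `dt_day`, `vR`.
#' @export
estimate_vR <- function(sample, ext_rate) {
  if (ext_rate <= 0) stop("extension rate must be positive", call. = FALSE)
  st <- sample_stations(sample)
  n <- length(st$s)
  if (n < 2L) stop("need at least two internodes", call. = FALSE)
  R <- sample$internodes$diameter_m / 2
  i <- seq_len(n - 1L)
  dt_i <- st$len[i] / ext_rate
  vR <- (R[i] - R[i + 1L]) / dt_i
  data.frame(s = st$s[i], x = st$x[i], x_mid = st$x[i] - st$len[i] / 2,
             dt_day = dt_i, vR = vR)
}

#' Fit the material profiles of a shoot
#'
#' Least-squares fits of the five material laws against distance from tip:
#' quadratics for volume density (from segment masses), radius and radial
#' expansion rate (reporting R^2), and sigmoids for flexural rigidity and
#' single-leaf mass (nonlinear least squares, reporting the RMSD).
#'
#' Flexural-rigidity observations come from `sample$stiffness` when supplied;
#' otherwise they are derived along the shoot as `E_str * I(x)` with `E_str`
#' from the basal bending record and `I` from the internode diameters.
#'
#' @param sample a [morphology_sample]; volume-density fitting requires the
#'   `mass_kg` column, leaf-mass fitting the `leaf_mass_kg` column.
#' @param ext_rate tip extension rate (m day^-1) used to reconstruct the
#'   radial expansion rate; if `NULL` the `vR` profile is not fitted and is
#'   set to zero.
#' @return List with `profiles` (a [material_profiles]) and `report` (data
#'   frame of fit indices per profile).
#' @export
fit_profiles <- function(sample, ext_rate = NULL) {
  st <- sample_stations(sample)
  x <- st$x
  R <- sample$internodes$diameter_m / 2
  rep_rows <- list()

  fit_quad <- function(x, y, what) {
    if (length(unique(x)) < 3L)
      stop("under-determined quadratic fit for profile '", what,
           "': need >= 3 distinct stations", call. = FALSE)
    fit <- stats::lm(y ~ I(x^2) + x)
    co <- stats::coef(fit)
    sst <- sum((y - mean(y))^2)
    r2 <- if (sst > 0) 1 - sum(stats::resid(fit)^2) / sst else 1
    rep_rows[[length(rep_rows) + 1L]] <<-
      data.frame(profile = what, index = "R2", value = r2)
    c(co[["I(x^2)"]], co[["x"]], co[["(Intercept)"]])
  }

  fit_sig <- function(x, y, what) {
    if (length(unique(x)) < 4L || all(y == y[1]))
      stop("under-determined sigmoid fit for profile '", what,
           "': need >= 4 distinct stations with variation", call. = FALSE)
    a0 <- max(y) * 1.05
    c0 <- stats::approx(y, x, xout = a0 / 2, ties = "ordered")$y
    if (!is.finite(c0)) c0 <- stats::median(x)
    b0 <- 4 / max(diff(range(x)), 1e-9)
    fit <- minpack.lm::nlsLM(
      y ~ a / (1 + exp(b * (cc - x))),
      start = list(a = a0, b = b0, cc = c0),
      control = minpack.lm::nls.lm.control(maxiter = 500))
    co <- stats::coef(fit)
    rmsd <- sqrt(mean(stats::resid(fit)^2))
    rep_rows[[length(rep_rows) + 1L]] <<-
      data.frame(profile = what, index = "RMSD", value = rmsd)
    c(co[["a"]], co[["b"]], co[["cc"]])
  }

  quad_R <- fit_quad(x, R, "R")

  if (!is.null(sample$internodes$mass_kg)) {
    rho3 <- sample$internodes$mass_kg / (pi * R^2 * st$len)
    quad_rho3 <- fit_quad(x, rho3, "rho3")
  } else stop("under-determined fit for profile 'rho3': segment masses absent",
              call. = FALSE)

  if (!is.null(ext_rate)) {
    v <- estimate_vR(sample, ext_rate)
    quad_vR <- fit_quad(v$x_mid, v$vR, "vR")
  } else quad_vR <- c(0, 0, 0)

  if (!is.null(sample$stiffness)) {
    sig_B <- fit_sig(sample$stiffness$x_m, sample$stiffness$EI_Nm2, "B")
  } else if (!is.null(sample$bending)) {
    bs <- bending_stiffness(sample$bending$EI_Nm2, sample$bending$d_v_m,
                            sample$bending$d_h_m)
    E_str <- mean(bs$E_str)
    sig_B <- fit_sig(x, E_str * pi * (2 * R)^4 / 64, "B")
  } else stop("under-determined fit for profile 'B': no stiffness observations",
              call. = FALSE)

  if (!is.null(sample$internodes$leaf_mass_kg)) {
    sig_ml <- fit_sig(x, sample$internodes$leaf_mass_kg, "ml")
  } else sig_ml <- c(0, 1, 0)

  list(profiles = material_profiles(quad_rho3, quad_R, quad_vR, sig_B, sig_ml),
       report = do.call(rbind, rep_rows))
}

#' Estimate the growth parameters from extension series
#'
#' Species-level pooling of per-shoot estimates. Per shoot: the extension rate
#' is the mean of `Delta(total length) / Delta(t)` over observation intervals;
#' the extension-zone length is the summed length, at the first date, of the
#' internodes classified as extending (relative length increase above
#' `threshold` in any interval). Shoots whose basal internode extends are
#' discarded. The local extension factor is `G0 = ell_dot / lg`.
#'
#' @param series list of [extension_series] objects (one per shoot).
#' @param threshold relative length increase above which an internode counts
#'   as extending (default 1%).
#' @return List with `ell_dot` (m day^-1), `lg` (m), `G0` (day^-1), `n_used`,
#'   `n_discarded`, and per-shoot tables.
#' @export
estimate_growth <- function(series, threshold = 0.01) {
  if (inherits(series, "extension_series")) series <- list(series)
  per <- lapply(series, function(es) {
    L <- es$lengths
    rel <- (L[, -1, drop = FALSE] - L[, -ncol(L), drop = FALSE]) /
      pmax(L[, -ncol(L), drop = FALSE], .Machine$double.eps)
    extending <- apply(rel > threshold, 1, any)
    if (extending[1])
      return(NULL)                      # basal internode still elongating
    ell_dot <- mean(diff(es$totals) / diff(es$dates))
    lg <- sum(L[extending, 1])
    data.frame(shoot_id = es$shoot_id, ell_dot = ell_dot, lg = lg)
  })
  used <- do.call(rbind, per)
  if (is.null(used) || nrow(used) == 0L)
    stop("all extension series discarded: basal internodes still elongating",
         call. = FALSE)
  ell_dot <- mean(used$ell_dot)
  lg <- mean(used$lg)
  if (lg <= 0) stop("no extending internodes found in any retained shoot", call. = FALSE)
  list(ell_dot = ell_dot, lg = lg, G0 = ell_dot / lg,
       n_used = nrow(used), n_discarded = length(series) - nrow(used),
       per_shoot = used)
}

#' Reach/orientation mismatch objective
#'
#' `F = (Reach_s - Reach_e)^2 + (Orient_s - Orient_e)^2`, mixing m^2 and rad^2
#' exactly as defined; an optional `scale` pair rescales the two terms.
#'
#' @param simulated,experimental numeric pairs `(reach, orientation)` in
#'   (m, rad).
#' @param scale optional positive pair of weights for the two squared terms.
#' @return Non-negative scalar; zero iff both components match.
#' @export
objective_F <- function(simulated, experimental, scale = c(1, 1)) {
  d <- (as.numeric(simulated)[1:2] - as.numeric(experimental)[1:2])^2
  sum(scale * d)
}

#' Estimate the sensing parameters from reach and orientation
#'
#' For each proprioceptive gain on `gamma_grid`, minimises
#' [objective_F] over `(alpha, beta)` by a derivative-free simplex search from
#' the initial guess, then returns the best of the per-gamma minima.
#'
#' @param runner function `(alpha, beta, gamma) -> c(reach, orientation)`,
#'   typically from [make_shoot_runner()]; must be deterministic.
#' @param reach_e,orient_e experimental reach (m) and orientation (rad).
#' @param guess numeric pair `(alpha0, beta0)` initial guess.
#' @param gamma_grid numeric vector of gamma values to scan.
#' @param reltol,maxit simplex-search control.
#' @return List with `alpha`, `beta`, `gamma`, `F`, and the `per_gamma` table.
#' @export
estimate_sensing <- function(runner, reach_e, orient_e, guess,
                             gamma_grid, reltol = 1e-12, maxit = 400L) {
  target <- c(reach_e, orient_e)
  best <- NULL
  rows <- list()
  scale <- pmax(abs(guess), 1e-6)
  for (gam in gamma_grid) {
    fn <- function(p) objective_F(runner(p[1], p[2], gam), target)
    opt <- tryCatch(
      stats::optim(guess, fn, method = "Nelder-Mead",
                   control = list(reltol = reltol, maxit = maxit,
                                  parscale = scale)),
      error = function(e) NULL)
    if (is.null(opt)) next
    rows[[length(rows) + 1L]] <- data.frame(
      gamma = gam, alpha = opt$par[1], beta = opt$par[2], F = opt$value)
    if (is.null(best) || opt$value < best$F)
      best <- list(alpha = opt$par[1], beta = opt$par[2], gamma = gam,
                   F = opt$value)
  }
  if (is.null(best))
    stop("sensing-parameter optimisation failed for every gamma", call. = FALSE)
  best$per_gamma <- do.call(rbind, rows)
  best
}

#' Structural Young's modulus from a bending record
#'
#' The second moment of area of the (nearly circular) elliptical section for
#' bending in the vertical plane is `I = pi * d_h * d_v^3 / 64`; the
#' structural modulus is the measured flexural rigidity divided by it.
#'
#' @param EI measured flexural rigidity, N m^2 (vectorised over positions).
#' @param d_v,d_h vertical and horizontal diameters, m (positive).
#' @return Data frame with columns `EI`, `I`, `E_str` (N m^-2).
#' @export
bending_stiffness <- function(EI, d_v, d_h) {
  if (any(d_v <= 0) || any(d_h <= 0))
    stop("diameters must be positive", call. = FALSE)
  I <- pi * d_h * d_v^3 / 64
  data.frame(EI = EI, I = I, E_str = EI / I)
}

#' Flexural rigidity from raw four-point bending data
#'
#' Optional helper converting force-deflection pairs of a four-point bending
#' test to `EI`. With total applied force `F`, support span `L`, load span
#' `l` and `a = (L - l)/2`, the midspan deflection is
#' `delta = F a (3 L^2 - 4 a^2) / (24 EI)`; `EI` is obtained from the slope of
#' the regression of `F` on `delta` through the origin.
#'
#' @param force applied forces, N.
#' @param deflection midspan deflections, m.
#' @param support_span,load_span rig spans, m (`load_span < support_span`).
#' @return `EI` in N m^2.
#' @export
four_point_EI <- function(force, deflection, support_span, load_span) {
  stopifnot(load_span < support_span, support_span > 0)
  a <- (support_span - load_span) / 2
  slope <- sum(force * deflection) / sum(deflection^2)
  slope * a * (3 * support_span^2 - 4 * a^2) / 24
}
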