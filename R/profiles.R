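# Material laws along the shoot, parameterised by the distance from the tip
# x = ell(t) - s.  Volume density rho3, radius R and radial expansion rate v_R
# are quadratic in x; flexural rigidity B and single-leaf mass m_l are
# saturating sigmoids (both grow with maturation away from the tip).

#' Material profiles of a searcher shoot
#'
#' Bundles the coefficient triples of the five material laws used by the rod
#' model, all functions of the distance from the tip `x = ell(t) - s`:
#' volume density `rho3(x)`, cross-section radius `R(x)` and radial expansion
#' rate `vR(x)` as quadratics `a*x^2 + b*x + c`, and flexural rigidity `B(x)`
#' and single-leaf mass `ml(x)` as sigmoids `a / (1 + exp(b*(c - x)))`.
#'
#' @param quad_rho3 numeric triple `(a, b, c)` for the volume density,
#'   units kg m^-5, kg m^-4, kg m^-3.
#' @param quad_R triple for the radius, units m^-1, (dimensionless), m.
#' @param quad_vR triple for the radial expansion rate, units
#'   day^-1 m^-1, day^-1, m day^-1.
#' @param sig_B triple `(a, b, c)` for the flexural rigidity sigmoid,
#'   units N m^2, m^-1, m; amplitude `a` must be positive.
#' @param sig_ml triple for the single-leaf mass sigmoid, units kg, m^-1, m;
#'   amplitude `a` must be non-negative.
#' @return An object of class `material_profiles`.
#' @examples
#' pr <- material_profiles(
#'   quad_rho3 = c(0, 0, 1000),
#'   quad_R    = c(1.5e-4, 9.6e-4, 5.6e-4),
#'   quad_vR   = c(7.3e-5, -6.9e-5, 3.6e-5),
#'   sig_B     = c(3.8e-1, 4.1, 1.6),
#'   sig_ml    = c(6.2e-3, 5.7, 1.1))
#' profile_radius(pr, c(0, 0.5, 1))
#' @export
material_profiles <- function(quad_rho3, quad_R, quad_vR, sig_B, sig_ml) {
  chk3 <- function(v, nm) {
    if (!is.numeric(v) || length(v) != 3L || anyNA(v))
      stop("'", nm, "' must be a numeric triple (a, b, c)", call. = FALSE)
    as.numeric(v)
  }
  obj <- structure(list(
    quad_rho3 = chk3(quad_rho3, "quad_rho3"),
    quad_R    = chk3(quad_R, "quad_R"),
    quad_vR   = chk3(quad_vR, "quad_vR"),
    sig_B     = chk3(sig_B, "sig_B"),
    sig_ml    = chk3(sig_ml, "sig_ml")
  ), class = "material_profiles")
  if (obj$sig_B[1] <= 0)
    stop("flexural rigidity amplitude a_fr must be positive", call. = FALSE)
  if (obj$sig_ml[1] < 0)
    stop("leaf mass amplitude a_l must be non-negative", call. = FALSE)
  obj
}

#' @export
print.material_profiles <- function(x, ...) {
  cat("Material profiles (functions of distance from tip x):\n")
  f <- function(v) paste(format(v, digits = 3), collapse = ", ")
  cat("  rho3(x) quadratic: ", f(x$quad_rho3), "\n")
  cat("  R(x)    quadratic: ", f(x$quad_R), "\n")
  cat("  vR(x)   quadratic: ", f(x$quad_vR), "\n")
  cat("  B(x)    sigmoid  : ", f(x$sig_B), "\n")
  cat("  ml(x)   sigmoid  : ", f(x$sig_ml), "\n")
  invisible(x)
}

#' Evaluate a quadratic material law
#'
#' Returns `a*x^2 + b*x + c` for a coefficient triple `(a, b, c)`.
#'
#' @param coeffs numeric triple `(a, b, c)`.
#' @param x distance from the tip, m; must be non-negative.
#' @return Numeric vector of the same length as `x`.
#' @export
eval_quadratic <- function(coeffs, x) {
  stopifnot(is.numeric(coeffs), length(coeffs) == 3L)
  if (any(x < 0)) stop("distance from tip x must be non-negative", call. = FALSE)
  coeffs[1] * x^2 + coeffs[2] * x + coeffs[3]
}

#' Evaluate a sigmoid material law
#'
#' Returns `a / (1 + exp(b*(c - x)))`. The exponential is guarded so that the
#' result saturates cleanly at 0 or `a` instead of overflowing.
#'
#' @inheritParams eval_quadratic
#' @return Numeric vector of the same length as `x`.
#' @export
eval_sigmoid <- function(coeffs, x) {
  stopifnot(is.numeric(coeffs), length(coeffs) == 3L)
  if (any(x < 0)) stop("distance from tip x must be non-negative", call. = FALSE)
  z <- coeffs[2] * (coeffs[3] - x)
  z <- pmin(pmax(z, -700), 700)          # exp() overflow guard
  coeffs[1] / (1 + exp(z))
}

# Clamped evaluation of the quadratic laws.  The fitted polynomials are only
# trusted over the observed range of x; beyond it they may dip below zero,
# which would be unphysical for a density, radius or expansion rate.
clamped_quadratic <- function(coeffs, x, what) {
  v <- eval_quadratic(coeffs, x)
  if (any(v < 0)) {
    warning(sprintf("%s(x) < 0 for some x (fitted range exceeded); clamped to 0",
                    what), call. = FALSE)
    v <- pmax(v, 0)
  }
  v
}

#' Evaluate named material profiles
#'
#' Convenience evaluators for each of the five fitted laws. The quadratic laws
#' (`rho3`, `R`, `vR`) are clamped at zero with a warning outside their
#' physically meaningful range.
#'
#' @param profiles a [material_profiles] object.
#' @param x distance from the tip, m (vectorised).
#' @return Numeric vector of profile values at `x`.
#' @export
profile_rho3 <- function(profiles, x) clamped_quadratic(profiles$quad_rho3, x, "rho3")

#' @rdname profile_rho3
#' @export
profile_radius <- function(profiles, x) clamped_quadratic(profiles$quad_R, x, "R")

#' @rdname profile_rho3
#' @export
profile_vR <- function(profiles, x) clamped_quadratic(profiles$quad_vR, x, "vR")

#' @rdname profile_rho3
#' @export
profile_B <- function(profiles, x) eval_sigmoid(profiles$sig_B, x)

#' @rdname profile_rho3
#' @export
profile_ml <- function(profiles, x) eval_sigmoid(profiles$sig_ml, x)

# dB/dx of the sigmoid rigidity profile (analytic), used by the
# secondary-growth term dtB/B.
profile_B_prime <- function(profiles, x) {
  a <- profiles$sig_B[1]; b <- profiles$sig_B[2]; cc <- profiles$sig_B[3]
  z <- pmin(pmax(b * (cc - x), -700), 700)
  e <- exp(z)
  a * b * e / (1 + e)^2
}

#' Linear density of the rod
#'
#' Mass per unit length `rho(x) = rho3(x) * pi * R(x)^2`, from the volume
#' density and the circular cross-section of radius `R(x)`.
#'
#' @inheritParams profile_rho3
#' @return Linear density in kg m^-1.
#' @export
linear_density <- function(profiles, x) {
  profile_rho3(profiles, x) * pi * profile_radius(profiles, x)^2
}

#' Leaf node layout along the shoot
#'
#' Records where leaves are borne: internode bases at arc lengths `s` carrying
#' `n` leaves each. The first base sits at the clamp (`s[1] = 0`), bases are
#' strictly increasing and counts are non-negative integers.
#'
#' @param s numeric vector of internode-base arc lengths, m.
#' @param n integer vector of leaf counts at those bases.
#' @return An object of class `leaf_layout`.
#' @export
leaf_layout <- function(s, n) {
  stopifnot(length(s) == length(n))
  if (length(s) == 0L)
    return(structure(list(s = numeric(0), n = integer(0)), class = "leaf_layout"))
  if (s[1] != 0) stop("first internode base must be at s = 0", call. = FALSE)
  if (any(diff(s) <= 0)) stop("internode bases must be strictly increasing", call. = FALSE)
  if (any(n < 0) || any(n != round(n)))
    stop("leaf counts must be non-negative integers", call. = FALSE)
  structure(list(s = as.numeric(s), n = as.integer(round(n))), class = "leaf_layout")
}

#' Cumulative leaf load above a point
#'
#' Total leaf mass carried apically of arc length `s`:
#' `ml(s) = sum over bases s_i >= s of n_i * ml_hat(ell - s_i)`, where
#' `ml_hat` is the single-leaf mass profile evaluated at the node's current
#' distance from the tip. A non-increasing step function of `s` with jumps at
#' the `s_i`.
#'
#' @param s arc length(s) at which the load is evaluated, m (vectorised).
#' @param layout a [leaf_layout].
#' @param profiles a [material_profiles].
#' @param ell current shoot length, m.
#' @return Leaf mass in kg, same length as `s`.
#' @export
leaf_load <- function(s, layout, profiles, ell) {
  stopifnot(inherits(layout, "leaf_layout"))
  if (any(s < 0) || any(s > ell))
    stop("s must lie within [0, ell]", call. = FALSE)
  keep <- layout$s <= ell               # nodes not yet existing are ignored
  sn <- layout$s[keep]
  nn <- layout$n[keep]
  if (length(sn) == 0L) return(numeric(length(s)))
  masses <- nn * profile_ml(profiles, ell - sn)
  vapply(s, function(si) sum(masses[sn >= si]), numeric(1))
}
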