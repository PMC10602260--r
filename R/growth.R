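# Tip-extension kinematics.  The shoot lengthens only inside an apical zone of
# length lg where the local extension factor is G0; material below the zone is
# stationary.  The Lagrangian map s(S, t) carries the fixed material coordinate
# S in [0, ell0] to the current arc length.  Once ell > lg (the only regime
# modelled) the total length is exactly affine, ell(t) = ell0 + G0*lg*t, and
# the characteristic ODE ds/dt = G0 * clamp(s - (ell - lg), 0, lg) has a
# closed-form solution used to advance material points without
# time-discretization error.

#' Growth parameters of the apical extension zone
#'
#' @param G0 local extension factor, day^-1 (non-negative).
#' @param lg length of the apical extension zone, m (positive).
#' @param ell0 initial shoot length, m; must exceed `lg` — the regime in which
#'   the whole shoot elongates is not modelled.
#' @return An object of class `growth_params`.
#' @export
growth_params <- function(G0, lg, ell0) {
  stopifnot(is.numeric(G0), is.numeric(lg), is.numeric(ell0))
  if (G0 < 0) stop("G0 must be non-negative", call. = FALSE)
  if (lg <= 0) stop("lg must be positive", call. = FALSE)
  if (ell0 <= lg)
    stop("ell0 must exceed lg: only shoots longer than the extension zone are modelled",
         call. = FALSE)
  structure(list(G0 = G0, lg = lg, ell0 = ell0), class = "growth_params")
}

#' Asymptotic tip extension rate
#'
#' For a shoot longer than the extension zone, the total length grows linearly
#' at the rate `G0 * lg` (the analytic solution of the extension equation).
#'
#' @param params a [growth_params] object.
#' @return Extension rate in m day^-1.
#' @export
extension_rate <- function(params) params$G0 * params$lg

#' Lagrangian arc-length map
#'
#' Discretises the material interval `[0, ell0]` with `n + 1` nodes and tracks
#' the current arc length of each node. At `t = 0` the map is the identity.
#'
#' @param params a [growth_params] object.
#' @param n number of elements of the initial mesh.
#' @return An object of class `arclength_map` with fields `S` (material
#'   coordinates), `s` (current arc lengths), `t` (time, day), `h0` (initial
#'   node spacing, the reference for mesh refinement).
#' @export
arclength_map <- function(params, n = 100L) {
  stopifnot(inherits(params, "growth_params"), n >= 4L)
  S <- seq(0, params$ell0, length.out = n + 1L)
  structure(list(S = S, s = S, t = 0, h0 = params$ell0 / n),
            class = "arclength_map")
}

#' Current shoot length of a map
#' @param map an [arclength_map].
#' @return Length `ell(t)` in m.
#' @export
map_length <- function(map) map$s[length(map$s)]

#' Local extension factor field
#'
#' `G(s, t) = G0` for `s` in the apical zone `[ell(t) - lg, ell(t)]` (closed
#' interval) and 0 below it.
#'
#' @param map an [arclength_map].
#' @param params a [growth_params].
#' @param s arc length(s), m; must lie in `[0, ell(t)]`.
#' @return Extension factor in day^-1, same length as `s`.
#' @export
growth_field <- function(map, params, s) {
  ell <- map_length(map)
  if (any(s < 0) || any(s > ell + 1e-12 * max(1, ell)))
    stop("s must lie within [0, ell(t)]", call. = FALSE)
  ifelse(s >= ell - params$lg, params$G0, 0)
}

# Material velocity ds/dt at current arc length s: G0 * (s - (ell - lg)) inside
# the zone, zero below, G0*lg at the tip.
material_velocity <- function(map, params, s) {
  ell <- map_length(map)
  params$G0 * pmin(pmax(s - (ell - params$lg), 0), params$lg)
}

#' Advance the arc-length map in time
#'
#' Integrates the extension equation over a step `dt` exactly: with
#' `ell(t) = ell0 + G0*lg*t` the characteristic ODE for a material point is
#' linear with a time-dependent forcing and has a closed-form solution,
#' including the exit time at which a point leaves the extension zone and
#' freezes. Monotonicity of the map is preserved by construction and checked.
#'
#' @param map an [arclength_map].
#' @param params a [growth_params].
#' @param dt time step, day (positive).
#' @return The advanced [arclength_map].
#' @export
advance_extension <- function(map, params, dt) {
  if (dt <= 0) stop("dt must be positive", call. = FALSE)
  G0 <- params$G0; lg <- params$lg
  s <- map$s
  ell <- s[length(s)]
  if (G0 == 0) { map$t <- map$t + dt; return(map) }
  b0 <- ell - lg                        # zone base at the current time
  y0 <- s - b0                          # offset above the zone base
  grows <- y0 > 0
  # exit time: a point inside the zone is overtaken by the rising zone base
  # when (lg - y0) * exp(G0 tau) = lg
  tau <- rep(Inf, length(s))
  inz <- grows & y0 < lg
  tau[inz] <- log(lg / (lg - y0[inz])) / G0
  te <- pmin(dt, tau)
  s_new <- s
  g <- grows
  s_new[g] <- b0 + (y0[g] - lg) * exp(G0 * te[g]) + lg * (1 + G0 * te[g])
  if (any(diff(s_new) <= 0))
    stop("extension step produced a non-monotone arc-length map", call. = FALSE)
  map$s <- s_new
  map$t <- map$t + dt
  map
}

# Mesh refinement: growth stretches node spacing near the tip.  When a gap in
# current arc length exceeds `factor` times the initial spacing, midpoints (in
# S) are inserted with s, and any nodal fields, linearly interpolated.
# `fields` is a named list of nodal vectors interpolated alongside.
refine_map <- function(map, fields = list(), factor = 2) {
  repeat {
    gap <- diff(map$s)
    big <- which(gap > factor * map$h0)
    if (length(big) == 0L) break
    newS <- (map$S[big] + map$S[big + 1L]) / 2
    news <- (map$s[big] + map$s[big + 1L]) / 2
    S2 <- sort(c(map$S, newS))
    idx <- match(newS, S2)
    s2 <- numeric(length(S2))
    s2[-idx] <- map$s
    s2[idx] <- news
    fields <- lapply(fields, function(f) {
      f2 <- numeric(length(S2))
      f2[-idx] <- f
      f2[idx] <- (f[big] + f[big + 1L]) / 2
      f2
    })
    map$S <- S2
    map$s <- s2
  }
  list(map = map, fields = fields)
}
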