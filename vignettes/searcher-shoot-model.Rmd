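---
title: "Modelling searcher shoots: growth, statics, sensing and calibration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling searcher shoots: growth, statics, sensing and calibration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(morphorod)
```

## The model

`morphorod` models the self-supporting "searcher" shoot of a climbing plant
as a planar, inextensible, unshearable morphoelastic rod. Three coupled
ingredients drive its development:

**Tip extension.** Primary growth acts only in an apical zone of length
$\ell_g$ with a local extension factor $G_0$ (day$^{-1}$). Writing $s(S,t)$
for the current arc length of the material point with Lagrangian coordinate
$S$, the extension law is
$$\partial_t \partial_S s = G(s,t)\,\partial_S s, \qquad
G(s,t) = G_0 \,\mathbf{1}\{s \in [\ell(t)-\ell_g,\,\ell(t)]\},$$
with $s(S,0) = S$ and $s(0,t) = 0$. Only the regime $\ell(t) > \ell_g$ is
modelled (configurations with the whole shoot elongating are rejected); there
the total length is exactly affine, $\ell(t) = \ell_0 + G_0\ell_g t$, so the
shoot extends at the constant rate $\dot\ell = G_0 \ell_g$.

**Static balance.** The inclination $\theta(s,t)$, measured from the upward
vertical, satisfies the Kirchhoff balance of the heavy rod at every instant:
$$\partial_s\!\left[B\,(\kappa - \partial_s\theta)\right]
 = \left[\int_s^{\ell}\rho\,d\sigma + m_l(s)\right] g \sin\theta ,$$
with the base clamped at $\theta(0)=\theta_0$ and a moment-free tip,
$\kappa(\ell)=\partial_s\theta(\ell)$. Here $\kappa$ is the intrinsic
(weightless) curvature, $B$ the flexural rigidity, $\rho = \rho_3 \pi R^2$
the linear density, and $m_l$ the lumped mass of the leaves borne apically
of $s$.

**Sensing.** The intrinsic curvature evolves under a directed stimulus,
proprioception and secondary growth:
$$\partial_t\kappa = G\,\frac{v_R}{R^2}\,(\alpha\cos\theta - \beta\sin\theta)
 \;-\; G\,\gamma\,\partial_s\theta
 \;-\; \delta\,\frac{\partial_t B}{B}\,(\kappa - \partial_s\theta),$$
with $\kappa(\cdot,0)=0$. The stimulus pair can be read in polar form,
$\alpha\cos\theta-\beta\sin\theta = \tilde\beta\sin(\theta_p-\theta)$ with
$\tilde\beta=\sqrt{\alpha^2+\beta^2}$: the shoot is steered towards the
inclination $\theta_p$. The proprioceptive term straightens; the $\delta$
term opposes it ("negative proprioception") whenever the rigidity grows in
time, freezing the current shape into the intrinsic one and curling the tip.

Material properties depend only on the distance from the tip
$x = \ell(t)-s$: quadratics for $\rho_3$, $R$, $v_R$ and saturating sigmoids
$a/(1+e^{b(c-x)})$ for $B$ and the single-leaf mass $\hat m_l$, reflecting
maturation away from the apex.

## Parameters that matter

| parameter | units | meaning | species values shipped |
|---|---|---|---|
| $G_0$ | day$^{-1}$ | local extension factor | 0.15 (T.j.), 0.12 (C.g.) |
| $\ell_g$ | m | extension-zone length | 0.14, 0.17 |
| $\alpha,\beta$ | day | directed-stimulus gains | see `species_calibration()` |
| $\gamma$ | – | proprioceptive gain | 8e-3, 4e-3 |
| $\delta$ | – | secondary-growth coupling | 0 (not estimable from the data) |
| $\theta_0$ | rad | clamp angle from vertical | $\pi/4$, $\pi/2$ |

`species_calibration()` returns the two published parameter sets. The
initial length $\ell_0$ and the final time are simulation choices, not
measured constants; the shipped default runs use $\ell_0 = 0.3$ m and
$T = 38$ day, which carries either shoot to $\approx 1.1$ m — the maximal
reach scale reported for both species.

## Numerical choices

* **Growth is integrated exactly.** Because $\ell(t)$ is affine in the
  modelled regime, the characteristic ODE of a material point,
  $\dot s = G_0\,\mathrm{clamp}(s-(\ell-\ell_g),\,0,\,\ell_g)$, has a closed
  form including the exit time at which a point leaves the zone and freezes.
  The map therefore carries no time-discretization error; `dt` only controls
  the sensing/statics splitting.
* **Meshing.** The grid is fixed in the material coordinate; growth
  stretches spacing near the tip, and nodes are inserted by monotone
  midpoint interpolation whenever a gap exceeds twice the initial spacing
  (`ds`, default 5 mm).
* **Statics.** Piecewise-linear finite elements with a lumped load vector;
  damped Newton to a residual of $10^{-10}$ (max 50 iterations), warm-started
  from the previous step and with continuation in $g$ as a fallback. The
  branch tracked is the one continued from the previous time step. Against
  an independent shooting integration of the uniform heavy cantilever the
  tip angle agrees to $4\times10^{-8}$ rad at 2000 elements.
* **Gradient recovery.** The sensing equation needs $\partial_s\theta$ at
  nodes. It is recovered from the moment balance,
  $\partial_s\theta = \kappa + B^{-1}\int_s^\ell w\sin\theta\,d\sigma$,
  which is exact at the continuum level and reduces *identically* to
  $\kappa$ when the load vanishes. This makes the massless full model agree
  with the weightless reduced model to machine precision, a property the
  test suite asserts.
* **Splitting.** Per step: exact growth advance, mesh refinement, tip
  condition ($\kappa(\ell) \leftarrow \partial_s\theta(\ell)$), curvature
  update, then statics. The curvature update is backward Euler with the
  $\theta$-dependent terms evaluated at the previous equilibrium and the
  stiff $\delta$-relaxation treated implicitly. The weightless model uses
  the same splitting with $\partial_s\theta \equiv \kappa$. Self-convergence
  is first order in `dt` (errors halve when `dt` halves), verified in the
  tests over `dt` from 0.4 to 0.0125 day.
* **Degenerate inputs.** The fitted quadratics are trusted only over the
  observed range of $x$; beyond it $\rho_3$, $R$, $v_R$ are clamped at zero
  with a warning. A vanishing radius inside the extension zone aborts the
  run (the stimulus prefactor $v_R/R^2$ is undefined there).

## Calibration pipeline

`fit_profiles()` fits the quadratics by ordinary least squares (reporting
$R^2$) and the sigmoids by Levenberg–Marquardt nonlinear least squares
(reporting the RMSD). Rigidity observations are taken directly when
supplied, and otherwise derived along the shoot as $E_{str} I(x)$ with
$E_{str} = EI/I$ from the basal four-point-bending record and
$I = \pi d_h d_v^3/64$. Note that a sigmoid whose transition lies beyond
the sampled range of $x$ is only marginally identifiable — its amplitude and
midpoint trade off in the exponential tail — so coefficient-level recovery
requires shoots long enough to see the rigidity rise.

`estimate_vR()` reconstructs the radial expansion rate from consecutive
internode radii: $\Delta t_i = \mathrm{length}_i/\dot\ell$ is the time the
tip needs to advance one internode, and
$v_R(s_i) = (R_i - R_{i+1})/\Delta t_i$. Each estimate is attached to the
midpoint of the spanned $x$-interval, where the finite difference of a
smooth radius profile is second-order exact.

`estimate_growth()` pools shoots of a species: $\dot\ell$ is the mean of
$\Delta(\text{total length})/\Delta t$ over intervals and shoots; $\ell_g$
is the per-shoot summed length, at the first date, of the internodes that
elongated (relative increase above 1% in any interval — the classification
threshold is a package convention, configurable); shoots whose basal
internode elongates are discarded; finally $G_0 = \dot\ell/\ell_g$.

`estimate_sensing()` minimises
$F(\alpha,\beta,\gamma) = (\mathrm{Reach}_s-\mathrm{Reach}_e)^2 +
(\mathrm{Orient}_s-\mathrm{Orient}_e)^2$ — metres² plus radians², exactly as
defined; an optional `scale` argument rescales the two terms and is off by
default. For each $\gamma$ on an explicit grid a Nelder–Mead simplex
searches over $(\alpha,\beta)$ from the initial guess, and the best
per-$\gamma$ minimum wins. Since two observables constrain three gains, the
minimiser is generally non-unique along the grid — the pipeline reports the
$F$-value achieved, which is the meaningful quantity.

## The synthetic-data generator

`generate_morphology()` and `generate_extension_series()` emulate the two
field-table schemas with known ground truth, so every calibration stage is
testable round-trip. Design choices:

* Measurements are referred to internode *base* stations, the same
  convention `fit_profiles()` inverts, so zero-noise round trips recover the
  truth coefficients exactly.
* The truth expansion rate is not free: maturation depending only on
  distance from the tip forces $v_R(x) = \dot\ell\,R'(x)$, and the generator
  derives it from the radius profile.
* The extension series freezes the internode count over the short
  observation window and lets the apical internodes — summing exactly to
  $\ell_g$ at the first date — elongate proportionally; basal internodes stay
  fixed. Real apices initiate new internodes and real growth zones taper,
  so the generator is a clean-room idealisation: passing round-trip tests
  demonstrates the estimators invert the stated measurement model, not that
  field data are this benign.
* Noise is multiplicative log-normal on positive observables, and a single
  seed governs the generator, making outputs byte-reproducible.
* Leaf counts default to two per node (opposite phyllotaxy typical of the
  study group).

## Stability of the sine-law system

The classical gravitropic law with proprioception,
$\dot\kappa = -\beta\sin\theta - \gamma\kappa$, $\theta' = \kappa$, is
simulated by the method of lines (`simulate_sine_law`). Linearised about the
vertical, the system is a differential-algebraic pencil; with $\partial_s$
discretised by first-order upwind differences from the clamped end, the
algebraic row is eliminated exactly and the finite spectrum is that of
$-\beta D^{-1} - \gamma I$ — a lower-triangular matrix whose spectrum is its
diagonal, $-\beta h - \gamma$ with multiplicity $n$ (`linear_spectrum`).
Reading the diagonal is exact; a dense nonsymmetric eigensolver on this
maximally defective matrix would scatter the computed eigenvalues over a
region of order $\|A\|\,\varepsilon^{1/n}$ and corrupt even the sign. The
result: stable for $\gamma > 0$, unstable for $\gamma < 0$, marginal
($-\beta h \to 0^-$) at $\gamma = 0$; the boundary condition at the free end
does not enter the reduced operator, so the sign conclusion is insensitive
to it.

Two unprinted details are package choices. The initial perturbation of the
damping experiment is curvature concentrated at the base,
$\kappa_0(s) = e^{-5s}$: for $\gamma<0$ amplification is strongest where the
inclination stays small, i.e. near the clamp, whereas a uniform or
tip-concentrated perturbation is dominated by the oscillatory transient over
the short $[0,1]\times[0,2]$ window. The closed-form steady state
$\theta_0 e^{-\beta s/\gamma}$ solves the linearised steady-state equation;
the tests integrate the *nonlinear* steady-state ODE
$\theta' = -(\beta/\gamma)\sin\theta$ and verify 1% agreement for
$|\theta_0|\le 0.1$.

## Worked example

```{r example, eval = FALSE}
cal <- species_calibration("C_guianense")
tr <- simulate_shoot(cal$profiles, cal$growth, cal$sensing, cal$theta0,
                     T_final = 38, dt = 0.05, model = "full",
                     layout = leaf_layout(seq(0, 0.25, by = 0.05), rep(2, 6)))
tr
plot(tr$frames[[11]]$px, tr$frames[[11]]$py, type = "l", asp = 1,
     xlab = "x (m)", ylab = "y (m)")
```

## Known limitations

* Planar only: no circumnutation, torsion, branching or attachment events.
* The Young's modulus is folded into the fitted rigidity profile; spatial
  variation of $E$ beyond what $B(x)$ captures is not represented.
* Multiple static equilibria are possible for strongly loaded rods; the
  solver tracks the branch continued from the previous step and does not
  enumerate alternatives.
* $\delta$ cannot be estimated from reach/orientation data alone; it is a
  fixed input, with the published observation that $\delta \approx 0.25$
  best resembles the curling of the horizontal-growing species.
* The problem sizes used by the shipped checks (2000 statics elements,
  `dt = 0.05` day, 38-day horizons, a 3-point $\gamma$ grid) were chosen to
  resolve each quantity comfortably; all scale up linearly if finer answers
  are needed.
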