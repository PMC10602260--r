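# morphorod

Climbing plants cross gaps with specialised self-supporting stems —
"searcher" shoots — that combine tip extension (primary growth), radial
thickening and stiffening (secondary growth), and active sensing
(gravitropism and proprioception). `morphorod` implements a planar
morphoelastic-rod model of such a shoot for plant biomechanists who want to
simulate postural development, and to calibrate the model from the kind of
field data a searcher shoot actually yields: per-internode morphology,
dated internode lengths, reach and orientation, and four-point bending
tests.

## The model

The shoot is an inextensible planar rod whose inclination from the vertical
is θ(s, t). Three coupled equations drive it:

* **Extension** — growth acts in an apical zone of length ℓ_g with local
  factor G₀; the arc-length map s(S, t) obeys
  ∂ₜ∂_S s = G·∂_S s with G = G₀ on [ℓ−ℓ_g, ℓ], so the length grows at the
  constant rate ℓ̇ = G₀ℓ_g once ℓ > ℓ_g.
* **Static balance** — ∂ₛ[B(κ − ∂ₛθ)] = [∫ₛ^ℓ ρ dσ + m_l(s)] g sin θ, the
  Kirchhoff equilibrium of the heavy rod under its distributed mass
  ρ = ρ₃πR² and lumped leaf loads, clamped at θ₀ with a moment-free tip.
* **Sensing** — the intrinsic curvature evolves as
  ∂ₜκ = G(v_R/R²)(α cos θ − β sin θ) − Gγ∂ₛθ − δ(∂ₜB/B)(κ − ∂ₛθ):
  a directed stimulus steering towards θ_p = atan2(α, β), proprioceptive
  straightening, and a secondary-growth term that opposes proprioception and
  curls the tip.

Material laws (ρ₃, R, v_R, B, single-leaf mass) are functions of the
distance from the tip x = ℓ(t) − s — quadratics or saturating sigmoids —
fitted per shoot. The package ships the published calibrations for
*Trachelospermum jasminoides* and *Condylocarpon guianense*
(`species_calibration()`), a synthetic-data generator with known ground
truth, and the linear stability analysis of the classical sine-law system
κ̇ = −β sin θ − γκ.

## Worked example

```r
library(morphorod)
cal <- species_calibration("C_guianense")
extension_rate(cal$growth)
#> [1] 0.0204
tr <- simulate_shoot(cal$profiles, cal$growth, cal$sensing, cal$theta0,
                     T_final = 38, dt = 0.05, model = "full",
                     layout = leaf_layout(seq(0, 0.25, by = 0.05), rep(2, 6)))
tr
#> Shoot trajectory (full model): 11 frames, t in [0, 38] day
#>   final length 1.075 m, reach 1.059 m, orientation -2.6 deg from horizontal
```

The horizontal-clamped *C. guianense* shoot extends at 2.04 cm/day; over 38
days it reaches 1.06 m of its 1.08 m of stem while staying essentially
horizontal (−2.6° below the horizon) — the heavy stem droops under its own
weight while the upward stimulus (β > 0, preferred inclination
θ_p ≈ 14° from vertical) keeps the apex turning up. Frames in
`tr$frames` carry the centerline `(px, py)`, inclination and curvature for
plotting. `simulate_shoot(..., model = "weightless")` runs the reduced model
without statics — with the same calibration the shoot then rises
monotonically, which is how the package separates sensing-driven from
weight-driven posture.

Calibration runs the other way: `fit_profiles()` (quadratic and sigmoid
least squares with R²/RMSD reports), `estimate_growth()` (ℓ̇, ℓ_g, G₀ from
dated internode lengths), `estimate_vR()`, `bending_stiffness()`, and
`estimate_sensing()`, which minimises
F = (ΔReach)² + (ΔOrient)² over (α, β) on a γ grid against a model runner
from `make_shoot_runner()`. `generate_morphology()` /
`generate_extension_series()` produce seeded synthetic tables from known
truth for round-trip validation; small examples ship in `inst/extdata/`
(synthetic, as named).

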