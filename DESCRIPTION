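Package: morphorod
Title: Morphoelastic Rod Models of Climbing-Plant Searcher Shoots
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Planar morphoelastic rod model of the self-supporting "searcher"
    shoots of climbing plants. Couples tip extension (an apical growth zone of
    fixed length), static Kirchhoff balance of the heavy elastic rod under
    self-weight and lumped leaf loads, and an evolution law for the intrinsic
    curvature driven by a directed stimulus, proprioception and secondary
    growth (radial expansion and rigidification). Includes the full calibration
    pipeline from internode morphology and extension time series (profile
    fitting, radial-expansion-rate reconstruction, growth and sensing parameter
    estimation, bending-derived stiffness), a synthetic-data generator with
    known ground truth, and the linear stability analysis of the sine-law
    gravitropic system.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    deSolve,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    yaml,
    optparse,
    jsonlite
Config/testthat/edition: 3
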