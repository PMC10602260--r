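#' Published calibration for the two study species
#'
#' Parameter sets calibrated from field samples of the two Apocynaceae
#' climbers the model was developed on: *Trachelospermum jasminoides*
#' (clamped at pi/4 from the vertical, downward-directed stimulus, beta < 0)
#' and *Condylocarpon guianense* (clamped horizontally, upward-directed
#' stimulus, beta > 0). Units are SI with time in days. The profile
#' coefficients are per-sample fits; the growth parameters are species-level
#' averages.
#'
#' @param species `"T_jasminoides"` or `"C_guianense"`.
#' @return List with `profiles` ([material_profiles]), `growth`
#'   ([growth_params], with a nominal `ell0` of 0.3 m — the initial length is
#'   a simulation choice, not a measured constant), `sensing`
#'   ([sensing_params], `delta = 0`), `theta0` (rad) and `ell_dot`
#'   (the species-level extension rate, m day^-1).
#' @examples
#' cal <- species_calibration("C_guianense")
#' extension_rate(cal$growth)   # = G0 * lg
#' @export
species_calibration <- function(species = c("T_jasminoides", "C_guianense")) {
  species <- match.arg(species)
  if (species == "T_jasminoides") {
    list(
      species = species,
      profiles = material_profiles(
        quad_rho3 = c(1.2e4, -2.1e3, 1.6e3),
        quad_R    = c(-6e-4, 1.4e-4, 6e-4),
        quad_vR   = c(1.3e-4, 6e-5, 2.6e-5),
        sig_B     = c(1.6e-2, 4.2, 6.8e-1),
        sig_ml    = c(5.8e-5, 1e1, 1e-1)),
      growth  = growth_params(G0 = 1.5e-1, lg = 1.4e-1, ell0 = 0.3),
      sensing = sensing_params(alpha = 5e-4, beta = -5e-3, gamma = 8e-3),
      theta0  = pi / 4,
      ell_dot = 2e-2)
  } else {
    list(
      species = species,
      profiles = material_profiles(
        quad_rho3 = c(6.1e1, -1.9e1, 1e3),
        quad_R    = c(1.5e-4, 9.6e-4, 5.6e-4),
        quad_vR   = c(7.3e-5, -6.9e-5, 3.6e-5),
        sig_B     = c(3.8e-1, 4.1, 1.6),
        sig_ml    = c(6.2e-3, 5.7, 1.1)),
      growth  = growth_params(G0 = 1.2e-1, lg = 1.7e-1, ell0 = 0.3),
      sensing = sensing_params(alpha = 1e-3, beta = 4e-3, gamma = 4e-3),
      theta0  = pi / 2,
      ell_dot = 2e-2)
  }
}
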