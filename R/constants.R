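#' Physical constants used throughout the package
#'
#' Internal energies are reported in kcal/mol and potentials in
#' kcal mol^-1 e^-1; coordinates and depths are in Angstrom, charges in
#' elementary charges.
#'
#' @format A named list with elements:
#' \describe{
#'   \item{coulomb_v}{e/(4 pi eps0) = 14.399645 V Angstrom per elementary
#'     charge; the Coulomb prefactor in SI-derived volt units.}
#'   \item{kcal_per_volt}{1 V = 23.061 kcal mol^-1 e^-1; the single
#'     conversion applied at the Poisson-solver output.}
#'   \item{coulomb_kcal}{Coulomb's constant C0 = 322 Angstrom kcal/mol e^-2
#'     used by the pairwise dielectric energy.}
#' }
#' @export
mem_constants <- list(
  coulomb_v     = 14.399645,
  kcal_per_volt = 23.061,
  coulomb_kcal  = 322
)
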