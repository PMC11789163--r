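# Physical constants used throughout.  All energies are kJ/mol, lengths
# Angstrom, angles degrees, temperatures Kelvin unless a function says
# otherwise.

#' Physical constants
#'
#' Named list of the physical constants the package pins to single values:
#' `kB` (Boltzmann constant, kJ mol^-1 K^-1), `coulomb` (Coulomb prefactor
#' e^2/(4 pi eps0) * N_A, kJ mol^-1 Angstrom e^-2), `avogadro` (mol^-1),
#' and `cm1_to_kjmol` (energy of one photon of wavenumber 1 cm^-1, as a
#' molar quantity, kJ mol^-1).
#'
#' @return A named list of numeric constants.
#' @export
#' @examples
#' evccp_constants()$kB
evccp_constants <- function() {
  list(
    kB = 0.0083144621,
    coulomb = 1389.35458,
    avogadro = 6.02214076e23,
    cm1_to_kjmol = 0.0119626566
  )
}

.kB <- 0.0083144621
.COULOMB <- 1389.35458
.AVOGADRO <- 6.02214076e23
.CM1_KJMOL <- 0.0119626566
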