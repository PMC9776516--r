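# Physical constants (CODATA 2018) in the package's working units:
# lengths in Angstrom, charges in protonic units e, energies in kT,
# concentrations in mol/L.

#' @keywords internal
.AVOGADRO <- 6.02214076e23

# e^2 / (4 pi eps0 k_B) in units of Angstrom * Kelvin: divide by T to get the
# vacuum Bjerrum length in Angstrom.
.BJERRUM_VAC_AK <- 1.6710094689828735e5

# molar mass of water, kg/mol
.M_WATER <- 0.01801528

#' Vacuum Bjerrum length
#'
#' Length at which the unscreened Coulomb energy of two unit charges in
#' vacuum equals kT; divide by the relative permittivity for the Bjerrum
#' length in a solvent.
#'
#' @param temperature Temperature in K.
#' @return Length in Angstrom.
#' @keywords internal
bjerrum_vacuum <- function(temperature) .BJERRUM_VAC_AK / temperature

#' Inverse Debye screening length
#'
#' \eqn{\kappa = \sqrt{8 \pi \ell_B N_A I \cdot 10^{-27}}}, with
#' \eqn{\ell_B} the Bjerrum length in the solvent. For a 1:1 salt the ionic
#' strength equals the common bulk concentration of the two species.
#'
#' @param ionic_strength Ionic strength in mol/L.
#' @param temperature Temperature in K.
#' @param sdie Relative permittivity of the solvent.
#' @return \eqn{\kappa} in 1/Angstrom.
#' @export
#' @examples
#' 1 / debye_kappa(0.1)  # Debye length ~9.7 Angstrom at 0.1 M, 300 K
debye_kappa <- function(ionic_strength, temperature = 300, sdie = 80) {
  stopifnot(ionic_strength >= 0, temperature > 0, sdie > 0)
  lB <- bjerrum_vacuum(temperature) / sdie
  n_bulk <- ionic_strength * .AVOGADRO * 1e-27 # ions per Angstrom^3
  sqrt(8 * pi * lB * n_bulk)
}
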