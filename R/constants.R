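# Physical constants in the package's reduced unit system:
# length in Angstrom, mass in amu, energy in kcal/mol.
# The derived time unit is sqrt(amu * A^2 / (kcal/mol)) ~ 48.89 fs.

.kB_kcal <- 0.0019872041      # Boltzmann constant, kcal mol^-1 K^-1
.N_avogadro <- 6.02214076e23  # mol^-1
.coulomb_kcal <- 332.0637     # e^2 prefactor in vacuum, kcal mol^-1 A
.eps_water <- 78.4            # relative permittivity of water
.time_unit_fs <- 48.89        # one reduced time unit in femtoseconds

#' Thermal energy at a given temperature
#'
#' @param temperature Temperature in Kelvin.
#' @return Thermal energy `kB * T` in kcal/mol.
#' @export
kT <- function(temperature = 300) .kB_kcal * temperature
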