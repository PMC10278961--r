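# Physical constants in the AMBER-compatible unit system used throughout:
# lengths in Angstrom, energies in kcal/mol, charges in elementary charges,
# temperatures in Kelvin, masses in amu.

#' Physical constants
#'
#' Unit system: Angstrom / kcal/mol / elementary charge / Kelvin / amu.
#'
#' @format A named list:
#' \describe{
#'   \item{kcoul}{Coulomb constant, 332.0637 kcal A / (mol e^2)}
#'   \item{kB}{Boltzmann constant, 0.0019872041 kcal/(mol K)}
#'   \item{h}{Planck constant, J s}
#'   \item{kB_si}{Boltzmann constant, J/K}
#'   \item{freq_conv}{sqrt(kcal/mol/A^2/amu) -> rad/s conversion}
#' }
#' @export
bfe_constants <- list(
  kcoul     = 332.0637,
  kB        = 0.0019872041,
  h         = 6.62607015e-34,
  kB_si     = 1.380649e-23,
  avogadro  = 6.02214076e23,
  # omega[rad/s] = freq_conv * sqrt(k[kcal/mol/A^2] / m[amu])
  freq_conv = sqrt(4.184e26),
  atm_pa    = 101325
)

# standard atomic masses (amu) for toy elements
.element_masses <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999,
  F = 18.998, P = 30.974, S = 32.06, CL = 35.45, NA. = 22.99
)

atomic_mass <- function(element) {
  m <- .element_masses[toupper(element)]
  m[is.na(m)] <- 12.011  # generic bead mass
  unname(m)
}

is_heavy <- function(element) toupper(element) != "H"
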