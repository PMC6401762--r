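# Physical constants (CODATA 2018) and unit conversions.
# Internal unit system: lengths in nm, energies in kBT, charges in units of e,
# times in s. Velocities are reported in nm/s, diffusivities in nm^2/s.

.const <- list(
  kB   = 1.380649e-23,      # J/K
  e    = 1.602176634e-19,   # C
  eps0 = 8.8541878128e-12,  # F/m
  Nav  = 6.02214076e23      # 1/mol
)

#' Unit conversions used throughout the package
#'
#' Small helpers converting between the user-facing units (nm or Angstrom,
#' volts or millivolts, Pa or atm, mol/L or nm^-3) and the internal unit
#' system (nm, kBT, e, s).
#'
#' @param x numeric vector to convert.
#' @return numeric vector in the target unit.
#' @name units
NULL

#' @rdname units
#' @export
molar_to_nm3 <- function(x) x * .const$Nav * 1e-24

#' @rdname units
#' @export
nm3_to_molar <- function(x) x / (.const$Nav * 1e-24)

#' @rdname units
#' @export
atm_to_pa <- function(x) x * 101325

#' @rdname units
#' @export
pa_to_atm <- function(x) x / 101325

#' @rdname units
#' @export
angstrom_to_nm <- function(x) x / 10

#' Thermal voltage kBT/e
#'
#' Conversion factor between the dimensionless electrostatic potential in
#' thermal units (kBT/e) and volts.
#'
#' @param T temperature in kelvin.
#' @return kBT/e in volts.
#' @export
thermal_voltage <- function(T = 298.15) .const$kB * T / .const$e

# beta * e * dV: applied voltage in thermal units (dimensionless)
beta_e_dV <- function(dV, T) dV / thermal_voltage(T)

# beta * dP in 1/nm^3 from a pressure in Pa
beta_dP_nm3 <- function(dP, T) dP * 1e-27 / (.const$kB * T)

stop_domain <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
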