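#' Bjerrum length
#'
#' Distance at which two unit charges in a dielectric medium interact with
#' thermal energy kBT: `lB = beta e^2 / (4 pi eps0 eps_w)`.
#'
#' @param T temperature in kelvin.
#' @param eps_w relative permittivity of the solvent (dimensionless).
#' @return Bjerrum length in nm (about 0.70 nm for water at 298.15 K).
#' @export
bjerrum_length <- function(T = 298.15, eps_w = 80) {
  if (any(T <= 0)) stop_domain("bjerrum_length: temperature must be positive")
  if (any(eps_w <= 0)) stop_domain("bjerrum_length: eps_w must be positive")
  .const$e^2 / (4 * pi * .const$eps0 * eps_w * .const$kB * T) * 1e9
}

#' Electrolyte description
#'
#' Bundles the ionic species, temperature, solvent viscosity and the
#' water/membrane permittivities. Either give a symmetric 1:1 salt through
#' `rho_b` (molar) or a full species table with valencies and molar
#' concentrations. The species list must be bulk-electroneutral.
#'
#' Derived members stored on the object: the Bjerrum length `lB` (nm), the
#' Debye-Hueckel screening parameter `kappa` (1/nm) and the dielectric
#' contrast `gamma_eps = eps_m / eps_w`.
#'
#' @param rho_b bulk concentration of a symmetric monovalent salt, in mol/L.
#' @param species optional data.frame with columns `valency` (integer) and
#'   `conc_M` (mol/L); overrides `rho_b`.
#' @param T temperature (K).
#' @param eta solvent viscosity (Pa s); default is water at room temperature.
#' @param eps_w,eps_m relative permittivities of the solvent and the membrane.
#' @return an object of class `electrolyte`.
#' @examples
#' el <- electrolyte(rho_b = 0.1)
#' 1 / el$kappa  # Debye length, ~0.96 nm
#' @export
electrolyte <- function(rho_b = NULL, species = NULL, T = 298.15,
                        eta = 8.91e-4, eps_w = 80, eps_m = 2) {
  if (T <= 0) stop_domain("electrolyte: temperature must be positive")
  if (eta <= 0) stop_domain("electrolyte: viscosity must be positive")
  if (!(eps_w > eps_m && eps_m > 0))
    stop_domain("electrolyte: permittivities must satisfy eps_w > eps_m > 0")
  if (is.null(species)) {
    if (is.null(rho_b)) rho_b <- 0
    if (rho_b < 0) stop_domain("electrolyte: rho_b must be non-negative")
    species <- data.frame(valency = c(1L, -1L), conc_M = c(rho_b, rho_b))
  }
  if (!all(c("valency", "conc_M") %in% names(species)))
    stop_domain("electrolyte: species needs columns 'valency' and 'conc_M'")
  if (any(species$conc_M < 0))
    stop_domain("electrolyte: species concentrations must be non-negative")
  if (abs(sum(species$valency * species$conc_M)) >
      1e-10 * max(1e-12, sum(abs(species$valency) * species$conc_M)))
    stop_domain("electrolyte: species list is not bulk-electroneutral")
  obj <- list(species = species, T = T, eta = eta,
              eps_w = eps_w, eps_m = eps_m)
  obj$lB <- bjerrum_length(T, eps_w)
  obj$gamma_eps <- eps_m / eps_w
  class(obj) <- "electrolyte"
  obj$kappa <- debye_parameter(obj)
  obj
}

#' Debye-Hueckel screening parameter
#'
#' `kappa^2 = 4 pi lB sum_i q_i^2 rho_i` with number densities in nm^-3; for
#' a symmetric 1:1 salt of density rho_b this reduces to
#' `kappa = sqrt(8 pi lB rho_b)`.
#'
#' @param elec an [electrolyte()] object.
#' @return kappa in 1/nm.
#' @export
debye_parameter <- function(elec) {
  stopifnot(inherits(elec, "electrolyte"))
  rho <- molar_to_nm3(elec$species$conc_M)
  sqrt(4 * pi * elec$lB * sum(elec$species$valency^2 * rho))
}

#' @export
print.electrolyte <- function(x, ...) {
  cat("Electrolyte:", paste(sprintf("%+d:%g M", x$species$valency,
                                    x$species$conc_M), collapse = ", "), "\n")
  cat(sprintf("  T = %.2f K, eta = %.3g Pa s, eps_w = %g, eps_m = %g\n",
              x$T, x$eta, x$eps_w, x$eps_m))
  cat(sprintf("  lB = %.4f nm, kappa = %.4f 1/nm (Debye length %.3f nm)\n",
              x$lB, x$kappa, if (x$kappa > 0) 1 / x$kappa else Inf))
  invisible(x)
}

#' Electrophoretic mobility coefficient
#'
#' `mu_e = eps0 eps_w kBT / (e eta)`, the coefficient relating the
#' electrophoretic polymer velocity to the applied field and the potential
#' drop across the annulus.
#'
#' @param elec an [electrolyte()] object.
#' @return mobility in m^2 / (V s) (about 2.0e-8 for water at 298 K).
#' @export
ep_mobility <- function(elec) {
  stopifnot(inherits(elec, "electrolyte"))
  .const$eps0 * elec$eps_w * .const$kB * elec$T / (.const$e * elec$eta)
}
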