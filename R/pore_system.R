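#' Nanopore-polymer system
#'
#' Geometry, surface charges and driving forces of a cylindrical polymer
#' (radius `a`, contour length `Lp`) translocating through a cylindrical
#' pore (radius `d`, membrane thickness `Lm`). Both surfaces are anionic:
#' `sigma_p` and `sigma_m` are stored as positive magnitudes and applied
#' internally with a negative sign. The voltage convention is
#' `dV = V_trans - V_cis` (positive dV drives an anionic polymer cis to
#' trans) and the pressure convention `dP = P_cis - P_trans` (positive dP
#' pushes the fluid cis to trans).
#'
#' @param a polymer radius (nm).
#' @param d pore radius (nm); must exceed `a`.
#' @param Lm membrane thickness (nm).
#' @param Lp polymer contour length (nm).
#' @param sigma_p magnitude of the polymer surface charge density (e/nm^2).
#' @param sigma_m magnitude of the membrane surface charge density (e/nm^2).
#' @param dV applied voltage (V).
#' @param dP applied pressure difference (Pa).
#' @param electrolyte an [electrolyte()] object.
#' @return an object of class `pore_system`. Derived members: `tau_lin`, the
#'   magnitude of the polymer line charge density `2 pi a sigma_p` (e/nm),
#'   and the occupancy geometry `zex = Lp + Lm`, `Lminus`, `Lplus`.
#' @examples
#' sys <- pore_system(a = 1, d = 5, Lm = 200, Lp = 180,
#'                    sigma_p = 0.4, sigma_m = 0.13, dV = -0.1,
#'                    dP = atm_to_pa(2), electrolyte = electrolyte(1.6))
#' sys
#' @export
pore_system <- function(a, d, Lm, Lp, sigma_p, sigma_m, dV = 0, dP = 0,
                        electrolyte = nanotransloc::electrolyte(0.1)) {
  if (!(a > 0 && d > a)) stop_domain("pore_system: need 0 < a < d (field 'a')")
  if (Lm <= 0) stop_domain("pore_system: Lm must be positive")
  if (Lp <= 0) stop_domain("pore_system: Lp must be positive")
  if (sigma_p < 0 || sigma_m < 0)
    stop_domain("pore_system: charge density magnitudes must be >= 0")
  stopifnot(inherits(electrolyte, "electrolyte"))
  obj <- list(a = a, d = d, Lm = Lm, Lp = Lp,
              sigma_p = sigma_p, sigma_m = sigma_m,
              dV = dV, dP = dP, electrolyte = electrolyte)
  obj$tau_lin <- 2 * pi * a * sigma_p
  obj$zex <- Lp + Lm
  obj$Lminus <- min(Lm, Lp)
  obj$Lplus <- max(Lm, Lp)
  class(obj) <- "pore_system"
  obj
}

#' @export
print.pore_system <- function(x, ...) {
  cat("Nanopore-polymer system\n")
  cat(sprintf("  polymer: a = %g nm, Lp = %g nm, sigma_p = %g e/nm^2 (tau = %.3f e/nm)\n",
              x$a, x$Lp, x$sigma_p, x$tau_lin))
  cat(sprintf("  pore:    d = %g nm, Lm = %g nm, sigma_m = %g e/nm^2\n",
              x$d, x$Lm, x$sigma_m))
  cat(sprintf("  driving: dV = %g mV, dP = %g Pa (%.3g atm)\n",
              x$dV * 1e3, x$dP, pa_to_atm(x$dP)))
  print(x$electrolyte)
  invisible(x)
}

# rebuild a pore_system with some fields replaced (used by the trapping
# root searches, which scan dP, rho_b or Lp)
update_system <- function(sys, ...) {
  repl <- list(...)
  args <- list(a = sys$a, d = sys$d, Lm = sys$Lm, Lp = sys$Lp,
               sigma_p = sys$sigma_p, sigma_m = sys$sigma_m,
               dV = sys$dV, dP = sys$dP, electrolyte = sys$electrolyte)
  if (!is.null(repl$rho_b)) {
    el <- sys$electrolyte
    args$electrolyte <- electrolyte(rho_b = repl$rho_b, T = el$T, eta = el$eta,
                                    eps_w = el$eps_w, eps_m = el$eps_m)
    repl$rho_b <- NULL
  }
  args[names(repl)] <- repl
  do.call(pore_system, args)
}
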