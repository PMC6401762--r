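# Stokes-flow quantities in the annulus between polymer and pore wall.
# All velocities use the cis-to-trans-positive sign convention.

#' Geometric factor of the annular streaming flow
#'
#' `gamma_geom = d^2/a^2 - 1 - 2 ln(d/a)`; vanishes as the annulus closes
#' (`d -> a`) and grows monotonically with `d/a`. Named `geometric_factor`
#' to avoid collision with the dielectric contrast.
#'
#' @param a polymer radius (nm).
#' @param d pore radius (nm), `d > a`.
#' @return dimensionless factor.
#' @export
geometric_factor <- function(a, d) {
  if (any(a <= 0) || any(d <= a))
    stop_domain("geometric_factor: need 0 < a < d")
  d^2 / a^2 - 1 - 2 * log(d / a)
}

# shared log-diffusivity helper: both diffusion coefficients are
# kBT * log(ratio) / (c * pi * eta * Lp); lengths in nm, result in nm^2/s.
# strict = TRUE demands ratio > 1 (the bulk coefficient must be positive);
# ratio = 1 is allowed otherwise (Dp vanishes at the pore wall).
.log_diffusion <- function(ratio, c, elec, Lp_nm, strict = FALSE) {
  if (any(ratio < 1) || (strict && any(ratio <= 1)))
    stop_domain("diffusion coefficient: length ratio must exceed 1 (log <= 0)")
  .const$kB * elec$T * log(ratio) / (c * pi * elec$eta * (Lp_nm * 1e-9)) * 1e18
}

#' Bulk and in-pore polymer diffusion coefficients
#'
#' `polymer_diffusion` is the transverse diffusion coefficient of the rigid
#' cylindrical polymer in the bulk, `D = kBT ln(Lp/2a) / (3 pi eta Lp)`;
#' `pore_diffusion` is the effective coefficient in the pore medium,
#' `Dp(r) = kBT ln(d/r) / (2 pi eta Lp)`, vanishing at the wall.
#'
#' @param system a [pore_system()].
#' @param r radius (nm) at which `Dp` is evaluated, default the polymer
#'   surface `a`.
#' @return diffusion coefficient in nm^2/s.
#' @export
polymer_diffusion <- function(system) {
  stopifnot(inherits(system, "pore_system"))
  .log_diffusion(system$Lp / (2 * system$a), 3, system$electrolyte, system$Lp,
                 strict = TRUE)
}

#' @rdname polymer_diffusion
#' @export
pore_diffusion <- function(system, r = system$a) {
  stopifnot(inherits(system, "pore_system"))
  .log_diffusion(system$d / r, 2, system$electrolyte, system$Lp)
}

#' Drift velocity from voltage and pressure
#'
#' Superposition of the electrophoretic/electroosmotic velocity and the
#' streaming-flow contribution:
#' `v_dr = mu_e (dV/Lm) [phi(d) - phi(a)] + gamma_geom a^2 dP / (4 eta Lm)`,
#' with `phi` the dimensionless annular DH potential of the full system.
#' Positive values mean cis-to-trans motion.
#'
#' @param system a [pore_system()].
#' @param field optional precomputed [dh_annulus_potential()] for `system`.
#' @return drift velocity in nm/s.
#' @export
drift_velocity <- function(system, field = NULL) {
  stopifnot(inherits(system, "pore_system"))
  if (is.null(field)) field <- dh_annulus_potential(system)
  el <- system$electrolyte
  mue <- ep_mobility(el)                                # m^2/(V s)
  dphi <- field$phi_at(system$d) - field$phi_at(system$a)
  Lm_m <- system$Lm * 1e-9; a_m <- system$a * 1e-9
  gam <- geometric_factor(system$a, system$d)
  v_ms <- mue * system$dV / Lm_m * dphi +
    gam * a_m^2 * system$dP / (4 * el$eta * Lm_m)
  v_ms * 1e9
}

#' Fluid velocity profile in the annulus
#'
#' Axial liquid velocity `uc(r)` from the Stokes equation with no-slip at
#' the wall (`uc(d) = 0`) and at the polymer surface (`uc(a) = vp(zp)`):
#' the superposition of the electroosmotic/electrophoretic term
#' `mu_e (dV/Lm) [phi(d) - phi(r)]`, the barrier-force term
#' `-beta Dp(r) Vp'(zp)` and the annular Poiseuille streaming profile
#' `(dP / 4 eta Lm) [d^2 - r^2 - 2 a^2 ln(d/r)]`.
#'
#' @param system a [pore_system()].
#' @param field a [dh_annulus_potential()] for the full system.
#' @param zp position of the polymer leading end (nm).
#' @param Vp optional interaction potential callable `Vp(zp)` in kBT (for
#'   its derivative at `zp`); defaults to the mean-field potential.
#' @param n radial grid size.
#' @return object of class `flow_profile`: data frame-ish list with grid
#'   `r` (nm), velocity `uc` (nm/s) and the polymer velocity `vp` (nm/s).
#' @export
fluid_velocity_profile <- function(system, field = NULL, zp = 0, Vp = NULL,
                                   n = 201) {
  stopifnot(inherits(system, "pore_system"))
  if (is.null(field)) field <- dh_annulus_potential(system)
  el <- system$electrolyte
  if (is.null(Vp)) Vp <- function(z) mf_interaction_potential(system, z)
  r <- seq(system$a, system$d, length.out = n)
  mue <- ep_mobility(el)
  Lm_m <- system$Lm * 1e-9
  # dVp/dzp (kBT/nm) by central difference, clamped to the domain
  h <- 1e-4 * system$zex
  z1 <- max(0, zp - h); z2 <- min(system$zex, zp + h)
  dVp <- (Vp(z2) - Vp(z1)) / (z2 - z1)
  ep <- mue * system$dV / Lm_m * (field$phi_at(system$d) - field$phi_at(r)) * 1e9
  barrier <- -pore_diffusion(system, r) * dVp      # nm^2/s * kBT/nm / kBT
  stream <- system$dP / (4 * el$eta * Lm_m) *
    (system$d^2 - r^2 - 2 * system$a^2 * log(system$d / r)) * 1e-18 * 1e9
  uc <- ep + barrier + stream
  vp <- drift_velocity(system, field) - pore_diffusion(system, system$a) * dVp
  structure(list(r = r, uc = uc, vp = vp, zp = zp, system = system),
            class = "flow_profile")
}

#' @export
as.data.frame.flow_profile <- function(x, ...) {
  data.frame(r_nm = x$r, uc_nm_per_us = x$uc * 1e-6)
}

#' @export
print.flow_profile <- function(x, ...) {
  cat(sprintf("Annular flow profile at zp = %g nm: uc(a) = %.4g nm/us, uc(d) = %.4g nm/us\n",
              x$zp, x$uc[1] * 1e-6, x$uc[length(x$uc)] * 1e-6))
  invisible(x)
}

#' @export
plot.flow_profile <- function(x, ...) {
  plot(x$r, x$uc * 1e-6, type = "l", xlab = "r (nm)",
       ylab = expression(u[c] ~ (nm / mu * s)), ...)
  invisible(x)
}
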