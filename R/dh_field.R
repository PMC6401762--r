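# Linearized Poisson-Boltzmann (Debye-Hueckel) electrostatics in the annular
# region a <= r <= d between the polymer surface and the pore wall.
#
# The screened radial equation (1/r) d/dr (r dphi/dr) = kappa^2 phi has the
# general solution phi = c1 I0(kappa r) + c2 K0(kappa r). The two constants
# are fixed by Gauss' law at the two charged surfaces:
#   phi'(a) = +4 pi lB sigma_p   (anionic polymer, thermal-unit potential)
#   phi'(d) = -4 pi lB sigma_m   (anionic wall)
# Exponentially scaled Bessel functions are used throughout so that large
# kappa*d never overflows: the two basis functions are normalized to be O(1)
# on [a, d].

#' Debye-Hueckel potential in the annular pore region
#'
#' Solves the linearized Poisson-Boltzmann equation for the dimensionless
#' electrostatic potential (thermal units kBT/e) between the polymer surface
#' `r = a` and the pore wall `r = d`, with Gauss boundary conditions from the
#' (anionic) polymer and membrane surface charges.
#'
#' @param system a [pore_system()].
#' @param n number of radial grid points stored on the returned field.
#' @return an object of class `radial_field`: a list with the radial grid
#'   `r` (nm), potential values `phi` (kBT/e), evaluators `phi_at(r)` and
#'   `dphi_at(r)` valid on `[a, d]`, and `kappa`, `lB`, `a`, `d`.
#' @seealso [membrane_potential()], [cumulative_charge()]
#' @export
dh_annulus_potential <- function(system, n = 201) {
  stopifnot(inherits(system, "pore_system"))
  a <- system$a; d <- system$d
  el <- system$electrolyte
  kappa <- el$kappa; lB <- el$lB
  sp <- system$sigma_p; sm <- system$sigma_m
  if (kappa <= 0) {
    if (sp == 0 && sm == 0) {
      return(new_radial_field(a, d, kappa, lB, system,
                              phi_at = function(r) rep(0, length(r)),
                              dphi_at = function(r) rep(0, length(r)), n = n))
    }
    stop_domain(paste("dh_annulus_potential: kappa = 0 with nonzero surface",
                      "charges has no screened solution; add salt"))
  }
  # scaled basis: f1 = I0(kr)/I0(kd), f2 = K0(kr)/K0(ka), both O(1) on [a,d]
  f1  <- function(r) besselI(kappa * r, 0, TRUE) /
    besselI(kappa * d, 0, TRUE) * exp(kappa * (r - d))
  f1p <- function(r) kappa * besselI(kappa * r, 1, TRUE) /
    besselI(kappa * d, 0, TRUE) * exp(kappa * (r - d))
  f2  <- function(r) besselK(kappa * r, 0, TRUE) /
    besselK(kappa * a, 0, TRUE) * exp(kappa * (a - r))
  f2p <- function(r) -kappa * besselK(kappa * r, 1, TRUE) /
    besselK(kappa * a, 0, TRUE) * exp(kappa * (a - r))
  M <- rbind(c(f1p(a), f2p(a)),
             c(f1p(d), f2p(d)))
  cf <- solve(M, c(4 * pi * lB * sp, -4 * pi * lB * sm))
  new_radial_field(a, d, kappa, lB, system,
                   phi_at = function(r) cf[1] * f1(r) + cf[2] * f2(r),
                   dphi_at = function(r) cf[1] * f1p(r) + cf[2] * f2p(r),
                   n = n)
}

new_radial_field <- function(a, d, kappa, lB, system, phi_at, dphi_at, n) {
  check <- function(r) {
    if (any(r < a - 1e-9) || any(r > d + 1e-9))
      stop_domain("radial_field: r outside [a, d] = [%g, %g]", a, d)
    pmin(pmax(r, a), d)
  }
  r <- seq(a, d, length.out = n)
  obj <- list(r = r, phi = phi_at(r),
              phi_at = function(r) phi_at(check(r)),
              dphi_at = function(r) dphi_at(check(r)),
              a = a, d = d, kappa = kappa, lB = lB, system = system)
  class(obj) <- "radial_field"
  obj
}

#' @export
print.radial_field <- function(x, ...) {
  cat(sprintf("Radial DH field on [%g, %g] nm (kappa = %.4f 1/nm)\n",
              x$a, x$d, x$kappa))
  cat(sprintf("  phi(a) = %.4f, phi(d) = %.4f kBT/e\n",
              x$phi_at(x$a), x$phi_at(x$d)))
  invisible(x)
}

#' @export
as.data.frame.radial_field <- function(x, ...) {
  data.frame(r_nm = x$r, phi_kT = x$phi)
}

#' @export
plot.radial_field <- function(x, ...) {
  plot(x$r, x$phi, type = "l", xlab = "r (nm)",
       ylab = expression(phi ~ (k[B] * T / e)), ...)
  invisible(x)
}

#' Potential of the membrane charges alone
#'
#' The annular DH potential with the polymer charge switched off
#' (`sigma_p = 0`); this is the field entering the mean-field
#' polymer-membrane interaction. Regular at `r = a` (zero inner derivative).
#'
#' @inheritParams dh_annulus_potential
#' @return a `radial_field`.
#' @export
membrane_potential <- function(system, n = 201) {
  stopifnot(inherits(system, "pore_system"))
  dh_annulus_potential(update_system(system, sigma_p = 0), n = n)
}

#' Mean-field polymer-membrane interaction potential
#'
#' Linear-response coupling of the in-pore polymer charge to the membrane
#' potential: `Vp(zp) = -2 pi a sigma_p * phi_m(a) * lp(zp)` in kBT, with
#' `lp(zp)` the in-pore polymer length from [pore_occupancy()]. For two
#' anionic surfaces (`phi_m(a) < 0`) this is a repulsive barrier, linear in
#' the in-pore length and flat on the constant-occupancy plateau.
#'
#' @param system a [pore_system()].
#' @param zp positions of the polymer leading end, in `[0, zex]` (nm).
#' @param phi_m optionally a precomputed [membrane_potential()] field.
#' @return interaction energy in kBT, vectorized over `zp`.
#' @export
mf_interaction_potential <- function(system, zp, phi_m = NULL) {
  stopifnot(inherits(system, "pore_system"))
  if (any(zp < 0) || any(zp > system$zex))
    stop_domain("mf_interaction_potential: zp outside [0, zex]")
  if (system$sigma_p == 0 || system$sigma_m == 0) return(rep(0, length(zp)))
  if (is.null(phi_m)) phi_m <- membrane_potential(system)
  lp <- pore_occupancy(system, zp)
  -2 * pi * system$a * system$sigma_p * phi_m$phi_at(system$a) * lp
}

#' Cumulative charge around the polymer
#'
#' Net charge (per unit e) enclosed within radius `r`, counting the full
#' polymer surface shell at `r = a` and the mobile ion cloud of the
#' linearized Boltzmann distribution consistent with `field`:
#' `Qcum(r) = -2 pi a sigma_p + 2 pi int_a^r r' rho_c(r') dr'`, with the
#' linearized mobile density `rho_c(r) = -kappa^2 phi(r) / (4 pi lB)`.
#' With a neutral wall, `Qcum(d) = 0` (global electroneutrality).
#'
#' @param system a [pore_system()].
#' @param field a `radial_field` for the full system (see
#'   [dh_annulus_potential()]).
#' @param r radii in `[a, d]` (nm), vectorized.
#' @return cumulative line charge density in e per nm of pore length,
#'   vectorized over `r`; `Qcum(a)` is the bare polymer line charge
#'   `-2 pi a sigma_p`.
#' @export
cumulative_charge <- function(system, field, r) {
  stopifnot(inherits(system, "pore_system"), inherits(field, "radial_field"))
  if (any(r < system$a - 1e-9) || any(r > system$d + 1e-9))
    stop_domain("cumulative_charge: r outside [a, d]")
  kappa <- field$kappa; lB <- field$lB
  rhoc <- function(rr) -kappa^2 * field$phi_at(rr) / (4 * pi * lB)
  base <- -2 * pi * system$a * system$sigma_p
  vapply(r, function(ri) {
    if (ri <= system$a) return(base)
    base + 2 * pi * stats::integrate(function(rr) rr * rhoc(rr), system$a, ri,
                                     rel.tol = 1e-10,
                                     subdivisions = 400L)$value
  }, numeric(1))
}
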