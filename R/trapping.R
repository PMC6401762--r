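# Critical trapping quantities: the driving-parameter values at which the
# mean translocation velocity changes sign and the polymer is trapped in
# the pore. The general-case answers are bracketed roots of vp(parameter);
# the high-salt and dilute-salt closed forms derived from the Debye-Hueckel
# expansions are exposed alongside.

.vp_of <- function(sys, ...) {
  mean_velocity(effective_potential(update_system(sys, ...), barrier = "mf"))
}

# bracketed root on a log- or linear grid; returns NA when no sign change
.grid_root <- function(f, grid) {
  v <- vapply(grid, f, numeric(1))
  s <- which(diff(sign(v)) != 0)
  if (length(s) == 0) return(NA_real_)
  i <- s[1]
  stats::uniroot(f, c(grid[i], grid[i + 1]), tol = 1e-10 *
                   max(abs(grid[i]), 1))$root
}

#' Critical trapping pressure
#'
#' Pressure difference at which the mean translocation velocity vanishes
#' and the polymer is trapped, found as a bracketed root of
#' `vp_mean(dP) = 0`. Near the root the velocity is linear in the pressure
#' with slope `gamma_geom a^2 / (4 eta Lm)`.
#'
#' @param system a [pore_system()].
#' @param interval pressure search interval in Pa (default +-10 atm).
#' @param n_grid number of bracketing grid points.
#' @return list with the root `dP_star` (Pa; `NA` with a message element if
#'   no sign change is found in the interval) and the local slope
#'   `slope` (nm/s per Pa).
#' @export
critical_pressure <- function(system, interval = atm_to_pa(c(-10, 10)),
                              n_grid = 41) {
  stopifnot(inherits(system, "pore_system"))
  root <- .grid_root(function(p) .vp_of(system, dP = p),
                     seq(interval[1], interval[2], length.out = n_grid))
  el <- system$electrolyte
  slope <- geometric_factor(system$a, system$d) * (system$a * 1e-9)^2 /
    (4 * el$eta * system$Lm * 1e-9) * 1e9      # nm/s per Pa
  if (is.na(root))
    return(list(dP_star = NA_real_, slope = slope,
                message = "no trapping in range"))
  list(dP_star = root, slope = slope)
}

#' Characteristic trapping salt densities
#'
#' The mean velocity of a voltage-driven, pressure-limited system vanishes
#' at up to two salt densities. The high-salt closed form follows from the
#' strong-screening drift velocity,
#' `rho_high = (2/(pi lB)) [(sigma_p - sigma_m) beta e dV /
#' (gamma_geom a^2 beta dP)]^2`, and the dilute closed form from the
#' small-kappa expansion with coefficients
#' `ap = -a/2 + a d^2 ln(d/a)/(d^2 - a^2)` and
#' `am = d/2 - a^2 d ln(d/a)/(d^2 - a^2)`. Both are also located
#' numerically as roots of `vp_mean(rho_b) = 0`.
#'
#' @param system a [pore_system()].
#' @param interval molar search range for the numerical roots.
#' @return list with closed forms `rho_high_closed`, `rho_low_closed` (mol/L)
#'   and numerical roots `rho_high`, `rho_low` (mol/L, `NA` when absent).
#' @export
trapping_salt_densities <- function(system, interval = c(1e-4, 4)) {
  stopifnot(inherits(system, "pore_system"))
  el <- system$electrolyte
  a <- system$a; d <- system$d
  gam <- geometric_factor(a, d)
  bedV <- beta_e_dV(system$dV, el$T)
  bdP <- beta_dP_nm3(system$dP, el$T)
  rho_high <- if (bdP != 0)
    2 / (pi * el$lB) *
      ((system$sigma_p - system$sigma_m) * bedV / (gam * a^2 * bdP))^2
  else NA_real_
  ap <- -a / 2 + a * d^2 * log(d / a) / (d^2 - a^2)
  am <- d / 2 - a^2 * d * log(d / a) / (d^2 - a^2)
  den <- gam * a^2 * bdP + 4 * (ap * system$sigma_p - am * system$sigma_m) * bedV
  rho_low <- if (den != 0)
    4 * d * a * log(d / a) * system$Lm * system$sigma_p * system$sigma_m /
      ((d^2 - a^2) * system$Lp * den)
  else NA_real_
  # numerical roots: scan log-spaced densities for sign changes of vp;
  # a +/- crossing (velocity killed by added salt) is the high-salt trapping
  # density, a -/+ crossing (barrier screened away) the dilute one
  grid <- exp(seq(log(interval[1]), log(interval[2]), length.out = 40))
  v <- vapply(grid, function(m) .vp_of(system, rho_b = m), numeric(1))
  s <- which(diff(sign(v)) != 0)
  roots <- vapply(s, function(i)
    stats::uniroot(function(m) .vp_of(system, rho_b = m),
                   c(grid[i], grid[i + 1]), tol = 1e-12)$root, numeric(1))
  falling <- v[s] > 0
  list(rho_high_closed = if (is.na(rho_high) || rho_high < 0) NA_real_
         else nm3_to_molar(rho_high),
       rho_low_closed = if (is.na(rho_low) || rho_low < 0) NA_real_
         else nm3_to_molar(rho_low),
       rho_high = if (any(falling)) max(roots[falling]) else NA_real_,
       rho_low = if (any(!falling)) min(roots[!falling]) else NA_real_,
       ap = ap, am = am)
}

#' Critical polymer length for trapping
#'
#' The electrostatic barrier scales with the in-pore portion while the
#' drift force acts on the whole molecule, so short polymers are rejected:
#' below `Lp_star` the mean velocity is negative. Found numerically as the
#' root of `vp_mean(Lp) = 0`; the dilute-salt closed form (the analogue of
#' the dilute trapping density with `Lp` and `rho_b` exchanged) is exposed
#' alongside. With a neutral wall there is no mean-field barrier and no
#' finite critical length.
#'
#' @param system a [pore_system()].
#' @param interval search interval for `Lp` (nm).
#' @return list with `Lp_star` (numerical root, nm or `NA`) and
#'   `Lp_star_dilute` (closed form, nm or `NA`).
#' @export
critical_length <- function(system, interval = c(2.5 * system$a, 2e4)) {
  stopifnot(inherits(system, "pore_system"))
  el <- system$electrolyte
  a <- system$a; d <- system$d
  gam <- geometric_factor(a, d)
  bedV <- beta_e_dV(system$dV, el$T)
  bdP <- beta_dP_nm3(system$dP, el$T)
  ap <- -a / 2 + a * d^2 * log(d / a) / (d^2 - a^2)
  am <- d / 2 - a^2 * d * log(d / a) / (d^2 - a^2)
  den <- gam * a^2 * bdP + 4 * (ap * system$sigma_p - am * system$sigma_m) * bedV
  rho_nm3 <- molar_to_nm3(system$electrolyte$species$conc_M[1])
  Lp_dilute <- if (den != 0 && rho_nm3 > 0)
    4 * d * a * log(d / a) * system$Lm * system$sigma_p * system$sigma_m /
      ((d^2 - a^2) * rho_nm3 * den)
  else NA_real_
  root <- if (system$sigma_m == 0) NA_real_ else
    .grid_root(function(L) .vp_of(system, Lp = L),
               exp(seq(log(interval[1]), log(interval[2]), length.out = 40)))
  list(Lp_star = root,
       Lp_star_dilute = if (is.na(Lp_dilute) || Lp_dilute < 0) NA_real_
         else Lp_dilute)
}
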