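# Steady-state Smoluchowski transport of the translocation coordinate zp on
# [0, zex], with the reservoir condition c(0) = ccis and an absorbing exit
# c(zex) = 0. All observables are Boltzmann-weighted integrals of the
# effective potential Up(zp); they are computed segment-exactly: the
# potential is tabulated on a grid with knots forced at the occupancy kinks
# L- and L+, interpolated piecewise-linearly, and each segment integral of
# exp(+-beta Up) is evaluated in closed form. This is exact for the
# mean-field piecewise-linear potential and for pure drift, and
# overflow-safe (a global shift of beta Up cancels in every observable).

#' Occupancy geometry of the pore
#'
#' Auxiliary lengths of the piecewise pore occupancy: `Lminus = min(Lm, Lp)`,
#' `Lplus = max(Lm, Lp)` and the exit coordinate `zex = Lp + Lm`.
#'
#' @param Lm membrane thickness (nm).
#' @param Lp polymer contour length (nm).
#' @return list with `Lminus`, `Lplus`, `zex`.
#' @export
occupancy_geometry <- function(Lm, Lp) {
  if (Lm <= 0 || Lp <= 0) stop_domain("occupancy_geometry: lengths must be positive")
  list(Lminus = min(Lm, Lp), Lplus = max(Lm, Lp), zex = Lm + Lp)
}

#' In-pore polymer length
#'
#' Piecewise-linear length of the polymer portion inside the pore as a
#' function of the leading-end position: `zp` during capture
#' (`zp < Lminus`), constant `Lminus` on the plateau, and `zex - zp` during
#' escape (`zp > Lplus`). Continuous, maximal value `Lminus`.
#'
#' @param geometry an [occupancy_geometry()] or a [pore_system()].
#' @param zp positions in `[0, zex]` (nm), vectorized.
#' @return in-pore length (nm).
#' @export
pore_occupancy <- function(geometry, zp) {
  g <- if (inherits(geometry, "pore_system"))
    occupancy_geometry(geometry$Lm, geometry$Lp) else geometry
  if (any(zp < -1e-9) || any(zp > g$zex + 1e-9))
    stop_domain("pore_occupancy: zp outside [0, zex]")
  pmin(zp, g$Lminus, g$zex - zp)
}

#' Effective potential of the translocation coordinate
#'
#' Combines the polymer-membrane interaction `Vp` and the drift velocity
#' into the potential governing the Smoluchowski dynamics:
#' `beta Up(zp) = (Dp(a)/D) beta Vp(zp) - (v_dr/D) zp`. For the mean-field
#' linear interaction this is the piecewise-linear form
#' `beta Up = lambda_b lp(zp) - lambda_d zp` with the inverse lengths
#' `lambda_d = v_dr/D` and `lambda_b = -2 pi a sigma_p phi_m(a) Dp(a)/D`.
#'
#' @param system a [pore_system()].
#' @param barrier which polymer-membrane interaction to include: `"mf"`
#'   (mean-field membrane coupling, the default), `"image"` (dielectric
#'   image-charge self-energy, plus the mean-field term if the wall is
#'   charged), or `"none"`.
#' @param Vp optional custom interaction potential: callable `Vp(zp)` in
#'   kBT on `[0, zex]`; overrides `barrier`.
#' @param n_barrier grid size used to tabulate the image-charge self-energy
#'   against the in-pore length (spline-interpolated afterwards).
#' @return object of class `effective_potential`: callables `beta_Up(zp)`
#'   and `Vp(zp)`, inverse lengths `lambda_d`, `lambda_b` (1/nm), transport
#'   coefficients `D`, `Dpa` (nm^2/s), drift velocity `vdr` (nm/s) and the
#'   occupancy geometry.
#' @export
effective_potential <- function(system, barrier = c("mf", "image", "none"),
                                Vp = NULL, n_barrier = 101) {
  stopifnot(inherits(system, "pore_system"))
  barrier <- match.arg(barrier)
  D <- polymer_diffusion(system)
  if (D <= 0) stop_domain("effective_potential: D must be positive")
  Dpa <- pore_diffusion(system)
  field <- dh_annulus_potential(system)
  vdr <- drift_velocity(system, field)
  geom <- occupancy_geometry(system$Lm, system$Lp)
  lambda_d <- vdr / D
  phim_a <- membrane_potential(system)$phi_at(system$a)
  lambda_b <- -2 * pi * system$a * system$sigma_p * phim_a * Dpa / D
  if (is.null(Vp)) {
    Vp <- switch(barrier,
      none = function(zp) rep(0, length(zp)),
      mf = function(zp) mf_interaction_potential(system, zp),
      image = {
        el <- system$electrolyte
        lp_grid <- seq(0, geom$Lminus, length.out = n_barrier)
        om <- vapply(lp_grid, function(l) {
          if (l <= 0) return(0)
          image_self_energy(self_energy_params(l, system$tau_lin, el$kappa,
                                               system$d, el$gamma_eps, el$lB))
        }, numeric(1))
        sfun <- stats::splinefun(lp_grid, om, method = "hyman")
        mfpart <- if (system$sigma_m > 0)
          function(zp) mf_interaction_potential(system, zp)
        else function(zp) rep(0, length(zp))
        function(zp) sfun(pore_occupancy(geom, zp)) + mfpart(zp)
      })
  }
  obj <- list(
    beta_Up = function(zp) (Dpa / D) * Vp(zp) - lambda_d * zp,
    Vp = Vp, lambda_d = lambda_d, lambda_b = lambda_b,
    D = D, Dpa = Dpa, vdr = vdr, geom = geom, zex = geom$zex,
    barrier = if (is.null(Vp)) barrier else "custom", system = system)
  class(obj) <- "effective_potential"
  obj
}

#' @export
print.effective_potential <- function(x, ...) {
  cat("Effective translocation potential\n")
  cat(sprintf("  lambda_d = %.4g 1/nm, lambda_b = %.4g 1/nm (%s regime)\n",
              x$lambda_d, x$lambda_b,
              if (x$lambda_d >= x$lambda_b) "drift-driven" else "barrier-driven"))
  cat(sprintf("  D = %.4g nm^2/s, Dp(a) = %.4g nm^2/s, vdr = %.4g nm/s\n",
              x$D, x$Dpa, x$vdr))
  invisible(x)
}

# ---- segment-exact Boltzmann quadrature ------------------------------------

# grid with knots forced at the occupancy kinks
.pot_grid <- function(pot, n) {
  g <- pot$geom
  z <- sort(unique(c(seq(0, g$zex, length.out = n), g$Lminus, g$Lplus)))
  z
}

# closed-form integral of exp(u) over one segment where u is linear
.seg_exp <- function(u1, u2, h) {
  b <- u2 - u1
  ifelse(abs(b) < 1e-10,
         h * exp((u1 + u2) / 2) * (1 + b^2 / 24),
         h * (exp(u2) - exp(u1)) / b)
}

# Shared machinery: tabulate shifted u = beta Up - c0 on the grid and return
# everything the observables need. The centered shift keeps every
# exponential representable for potential ranges up to ~1400 kBT.
.boltzmann_setup <- function(pot, n, shift = c("center", "max")) {
  shift <- match.arg(shift)
  z <- .pot_grid(pot, n)
  u <- pot$beta_Up(z)
  if (any(!is.finite(u))) stop_domain("transport: non-finite potential values")
  c0 <- if (shift == "center") (max(u) + min(u)) / 2 else max(u)
  u <- u - c0
  h <- diff(z)
  Iseg <- .seg_exp(u[-length(u)], u[-1], h)   # int exp(u) per segment
  C <- rev(cumsum(rev(c(Iseg, 0))))           # C[i] = int_{z_i}^{zex} exp(u)
  list(z = z, u = u, h = h, c0 = c0, Iseg = Iseg, C = C)
}

.logaddexp <- function(a, b) {
  m <- pmax(a, b)
  out <- m + log1p(exp(pmin(a, b) - m))
  out[is.infinite(m) & m < 0] <- -Inf
  out
}

# log of the relative density, log[c(z)/ccis], from a max-shifted setup
.log_density <- function(s) {
  (s$u[1] - s$u) + log(s$C) - log(s$C[1])
}

#' Polymer capture rate
#'
#' Steady-state polymer flux per unit cis concentration,
#' `Rc = D / int_0^zex exp(beta[Up(z) - Up(0)]) dz`, in velocity units.
#' Evaluated with the overflow-safe segment-exact quadrature.
#'
#' @param pot an [effective_potential()].
#' @param n grid size (the mean-field potential is integrated exactly for
#'   any `n`).
#' @return capture rate in nm/s.
#' @export
capture_rate <- function(pot, n = 2001) {
  stopifnot(inherits(pot, "effective_potential"))
  s <- .boltzmann_setup(pot, n)
  pot$D * exp(s$u[1]) / sum(s$Iseg)
}

#' Mean first-passage translocation time
#'
#' Double Boltzmann integral
#' `tau_p = (1/D) int_0^zex dz exp(-beta Up(z)) int_z^zex dz'' exp(beta Up(z''))`,
#' split into the capture (`z < Lminus`), constant-occupancy
#' (`Lminus < z < Lplus`) and escape (`z > Lplus`) contributions
#' `tau1 + tau2 + tau3 = tau_p`.
#'
#' @inheritParams capture_rate
#' @return list with `tau`, `tau1`, `tau2`, `tau3` (seconds).
#' @export
translocation_time <- function(pot, n = 2001) {
  stopifnot(inherits(pot, "effective_potential"))
  s <- .boltzmann_setup(pot, n)
  z <- s$z; u <- s$u; h <- s$h; C <- s$C
  nz <- length(z)
  i1 <- 1:(nz - 1)
  b <- u[i1 + 1] - u[i1]
  seg <- numeric(nz - 1)
  small <- abs(b) < 1e-8
  if (any(small)) {
    i <- i1[small]
    # u ~ constant: integrand = exp(-u) C(z); C(z) = C[i+1] + exp(u)(z[i+1]-z)
    seg[small] <- exp(-u[i]) * C[i + 1] * h[i] + h[i]^2 / 2
  }
  if (any(!small)) {
    i <- i1[!small]; bi <- b[!small] / h[i]
    A1 <- (exp(-u[i]) - exp(-u[i + 1])) / bi
    seg[!small] <- (C[i + 1] + exp(u[i + 1]) / bi) * A1 - h[i] / bi
  }
  g <- pot$geom
  mid <- (z[-nz] + z[-1]) / 2
  in1 <- mid < g$Lminus
  in2 <- mid >= g$Lminus & mid <= g$Lplus
  tau1 <- sum(seg[in1]) / pot$D
  tau2 <- sum(seg[in2]) / pot$D
  tau3 <- sum(seg[!(in1 | in2)]) / pot$D
  list(tau = tau1 + tau2 + tau3, tau1 = tau1, tau2 = tau2, tau3 = tau3)
}

#' Steady-state density profile and pore population
#'
#' `c(zp) = ccis int_zp^zex exp(beta[Up(z) - Up(zp)]) dz /
#'          int_0^zex exp(beta[Up(z) - Up(0)]) dz`, with `c(0) = ccis` and
#' the absorbing exit `c(zex) = 0`; the population is `N = int c` and the
#' steady flux `Jst = Rc ccis`.
#'
#' @inheritParams capture_rate
#' @param ccis cis-reservoir concentration (results scale linearly; default 1).
#' @return object of class `density_profile`: data frame `profile` with
#'   columns `zp_nm`, `Up_kT`, `c_over_ccis`, `vp_nm_per_us`, plus scalars
#'   `N`, `Jst`, `Rc`.
#' @export
density_profile <- function(pot, ccis = 1, n = 2001) {
  stopifnot(inherits(pot, "effective_potential"))
  s <- .boltzmann_setup(pot, n, shift = "max")
  conc <- ccis * exp(.log_density(s))
  # N = int c: trapezoid on the (dense) grid is adequate for the population
  N <- sum((conc[-1] + conc[-length(conc)]) / 2 * s$h)
  Rc <- pot$D * exp(s$u[1]) / s$C[1]
  # local velocity vp = -D d(beta Up)/dz, from segment slopes
  slopes <- diff(s$u) / s$h
  vp <- -pot$D * c(slopes[1], (slopes[-1] + slopes[-length(slopes)]) / 2,
                   slopes[length(slopes)])
  out <- list(profile = data.frame(zp_nm = s$z,
                                   Up_kT = s$u + s$c0,
                                   c_over_ccis = conc / ccis,
                                   vp_nm_per_us = vp * 1e-6),
              N = N, Jst = Rc * ccis, Rc = Rc, ccis = ccis)
  class(out) <- "density_profile"
  out
}

#' @export
print.density_profile <- function(x, ...) {
  cat(sprintf("Steady-state profile: N = %.4g ccis*nm, Jst = %.4g ccis*nm/s\n",
              x$N, x$Jst))
  invisible(x)
}

#' Average translocation velocity
#'
#' Density-weighted mean of the local velocity
#' `vp(zp) = -beta D Up'(zp)` over the pore,
#' `<vp> = int c vp / int c`. For a flat interaction this equals the drift
#' velocity exactly; in both the drift-dominated and barrier-dominated
#' regimes it is close to `D (lambda_d - lambda_b)`.
#'
#' @inheritParams capture_rate
#' @return mean velocity in nm/s.
#' @export
mean_velocity <- function(pot, n = 2001) {
  stopifnot(inherits(pot, "effective_potential"))
  s <- .boltzmann_setup(pot, n, shift = "max")
  lc <- .log_density(s)
  nz <- length(lc)
  # log of the per-segment population weight (trapezoid), normalized by its
  # maximum so deep potential wells never overflow
  lw <- .logaddexp(lc[-1], lc[-nz]) - log(2) + log(s$h)
  w <- exp(lw - max(lw))
  if (!any(w > 0)) stop_domain("mean_velocity: zero pore population")
  vseg <- -pot$D * diff(s$u) / s$h                     # vp is per-segment
  sum(w * vseg) / sum(w)
}

#' Full transport summary for a pore system
#'
#' One-call driver: builds the effective potential and returns the capture
#' rate, the translocation time and its capture/plateau/escape components,
#' the mean velocity, the pore population and the density profile.
#'
#' @inheritParams effective_potential
#' @param ccis cis concentration (default 1).
#' @param n transport grid size.
#' @return object of class `translocation` with members `Rc`, `tau`
#'   (list `tau, tau1, tau2, tau3`), `vp_mean`, `N`, `profile`
#'   (a [density_profile()]), `potential` and `system`.
#' @examples
#' sys <- pore_system(a = 0.5, d = 0.85, Lm = 5, Lp = 10,
#'                    sigma_p = 2.9 / pi, sigma_m = 0, dV = 0.12,
#'                    electrolyte = electrolyte(0.1))
#' tr <- translocation(sys, barrier = "image")
#' tr
#' @export
translocation <- function(system, barrier = c("mf", "image", "none"),
                          Vp = NULL, ccis = 1, n = 2001) {
  pot <- effective_potential(system, barrier = barrier, Vp = Vp)
  prof <- density_profile(pot, ccis = ccis, n = n)
  out <- list(Rc = capture_rate(pot, n = n),
              tau = translocation_time(pot, n = n),
              vp_mean = mean_velocity(pot, n = n),
              N = prof$N, profile = prof,
              potential = pot, system = system)
  class(out) <- "translocation"
  out
}

#' @export
print.translocation <- function(x, ...) {
  cat("Polymer translocation (steady-state Smoluchowski)\n")
  cat(sprintf("  capture rate  Rc = %.4g nm/s\n", x$Rc))
  cat(sprintf("  transl. time  tau = %.4g s (tau1 = %.3g, tau2 = %.3g, tau3 = %.3g)\n",
              x$tau$tau, x$tau$tau1, x$tau$tau2, x$tau$tau3))
  cat(sprintf("  mean velocity <vp> = %.4g nm/s, population N = %.4g ccis*nm\n",
              x$vp_mean, x$N))
  invisible(x)
}

#' @export
summary.translocation <- function(object, ...) {
  print(object)
  print(object$potential)
  invisible(object)
}
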