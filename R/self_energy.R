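# Dielectric image-charge self-energy of a charged line confined in a
# cylindrical cavity through a low-permittivity membrane. The membrane
# (eps_m ~ 2) polarizes against the in-pore polymer charge and the resulting
# repulsive self-energy acts as a salt-screened barrier against capture;
# in strong salt it decays as exp(-2 kappa d).

#' Parameters of the image-charge self-energy
#'
#' @param lp in-pore polymer length (nm), `lp >= 0`.
#' @param tau magnitude of the polymer line charge density (e/nm).
#' @param kappa inverse screening length (1/nm).
#' @param d pore radius (nm).
#' @param gamma_eps dielectric contrast `eps_m / eps_w`, in (0, 1).
#' @param lB Bjerrum length (nm).
#' @return an object of class `self_energy_params`.
#' @export
self_energy_params <- function(lp, tau, kappa, d,
                               gamma_eps = 2 / 80,
                               lB = bjerrum_length()) {
  if (lp < 0) stop_domain("self_energy_params: lp must be >= 0")
  if (kappa < 0) stop_domain("self_energy_params: kappa must be >= 0")
  if (d <= 0) stop_domain("self_energy_params: d must be positive")
  if (!(gamma_eps > 0 && gamma_eps < 1))
    stop_domain("self_energy_params: need 0 < gamma_eps < 1")
  structure(list(lp = lp, tau = tau, kappa = kappa, d = d,
                 gamma_eps = gamma_eps, lB = lB),
            class = "self_energy_params")
}

#' Dielectric jump function
#'
#' Spectral weight of the polarization charge induced on the pore wall,
#' entering the image-charge self-energy integral:
#' \deqn{\Delta(q) = \frac{p_b K_0(|q|d) K_1(p_b d) - \gamma_\epsilon |q| K_1(|q|d) K_0(p_b d)}
#'                      {p_b K_0(|q|d) I_1(p_b d) + \gamma_\epsilon |q| K_1(|q|d) I_0(p_b d)}}
#' with \eqn{p_b = \sqrt{\kappa^2 + q^2}}. Even in `q`; the `q = 0` limit is
#' the finite ratio `K1(kappa d)/I1(kappa d)`; decays exponentially for
#' `|q| d >> 1`.
#'
#' @param q axial wavenumber (1/nm), vectorized.
#' @param params a [self_energy_params()] (the `lp` and `tau` members are
#'   not used here).
#' @return dimensionless jump function values.
#' @export
dielectric_jump <- function(q, params) {
  stopifnot(inherits(params, "self_energy_params"))
  kappa <- params$kappa; d <- params$d; g <- params$gamma_eps
  vapply(abs(q), function(qq) {
    if (qq < 1e-12) {
      if (kappa <= 0) return(Inf)  # unscreened limit is log-divergent
      return(besselK(kappa * d, 1) / besselI(kappa * d, 1))
    }
    pb <- sqrt(kappa^2 + qq^2)
    # scaled forms: K(x) e^{x}, I(x) e^{-x}; exponentials combined by hand
    k0q <- besselK(qq * d, 0, TRUE); k1q <- besselK(qq * d, 1, TRUE)
    k0p <- besselK(pb * d, 0, TRUE); k1p <- besselK(pb * d, 1, TRUE)
    i0p <- besselI(pb * d, 0, TRUE); i1p <- besselI(pb * d, 1, TRUE)
    # numerator terms share e^{-(q+pb)d}; denominator terms e^{-(q-pb)d}
    num <- pb * k0q * k1p - g * qq * k1q * k0p
    den <- pb * k0q * i1p + g * qq * k1q * i0p
    num / den * exp(-2 * pb * d)
  }, numeric(1))
}

#' Image-charge self-energy of the in-pore polymer portion
#'
#' Fourier integral of the polymer line charge against its dielectric image:
#' \deqn{\beta\Delta\Omega_p(l_p) = l_p \ell_B \tau^2 \int_{-\infty}^{\infty}
#'   dq \, \frac{2\sin^2(q l_p / 2)}{\pi l_p q^2} \Delta(q)}
#' evaluated by adaptive quadrature on `[0, qmax]` (even integrand, doubled),
#' with the finite `q = 0` limit `lp^2/4 * Delta(0)` substituted analytically.
#' Non-negative for `gamma_eps < 1`; in strong salt
#' (`kappa lp >> 1`, `kappa d >> 1`) it approaches
#' `lp lB tau^2 K1(kappa d)/I1(kappa d) ~ pi lB lp tau^2 exp(-2 kappa d)`.
#'
#' @param params a [self_energy_params()].
#' @param rel.tol relative quadrature tolerance.
#' @return self-energy in kBT.
#' @export
image_self_energy <- function(params, rel.tol = 1e-8) {
  stopifnot(inherits(params, "self_energy_params"))
  lp <- params$lp; tau <- params$tau
  if (lp == 0 || tau == 0) return(0)
  d0 <- dielectric_jump(0, params)
  f <- function(q) {
    out <- numeric(length(q))
    tiny <- q < 1e-9
    if (any(tiny)) out[tiny] <- lp^2 / 4 * d0
    if (any(!tiny)) {
      qq <- q[!tiny]
      out[!tiny] <- sin(qq * lp / 2)^2 / qq^2 * dielectric_jump(qq, params)
    }
    out
  }
  qmax <- max(40 / params$d, 20 * params$kappa)
  I <- tryCatch(
    stats::integrate(f, 0, qmax, rel.tol = rel.tol,
                     subdivisions = 2000L)$value,
    error = function(e) stop_domain(
      "image_self_energy: quadrature failed (lp=%g, kappa=%g, d=%g): %s",
      lp, params$kappa, params$d, conditionMessage(e)))
  params$lB * tau^2 * 4 / pi * I
}

#' Strong-salt closed forms of the image-charge self-energy
#'
#' The two levels of the large-`kappa` approximation: the Bessel ratio
#' `lp lB tau^2 K1(kappa d)/I1(kappa d)` and its asymptotic
#' `pi lB lp tau^2 exp(-2 kappa d)`.
#'
#' @inheritParams image_self_energy
#' @return named numeric vector with elements `bessel_ratio` and
#'   `exponential`, in kBT.
#' @export
image_self_energy_strong_salt <- function(params) {
  stopifnot(inherits(params, "self_energy_params"))
  with(params, c(
    bessel_ratio = lp * lB * tau^2 * besselK(kappa * d, 1) /
      besselI(kappa * d, 1),
    exponential = pi * lB * lp * tau^2 * exp(-2 * kappa * d)))
}

#' Image-charge barrier profile along the translocation coordinate
#'
#' Assembles the polymer-membrane interaction from the self-energy of the
#' in-pore portion, `Vp(zp) = dOmega_p(lp(zp))` with `lp` the piecewise
#' pore occupancy, plus the mean-field membrane term when the wall is
#' charged.
#'
#' @param system a [pore_system()].
#' @param zp positions in `[0, zex]` (nm), vectorized.
#' @param rel.tol quadrature tolerance passed to [image_self_energy()].
#' @return barrier energy in kBT.
#' @export
image_barrier_potential <- function(system, zp, rel.tol = 1e-8) {
  stopifnot(inherits(system, "pore_system"))
  if (any(zp < 0) || any(zp > system$zex))
    stop_domain("image_barrier_potential: zp outside [0, zex]")
  el <- system$electrolyte
  lps <- pore_occupancy(system, zp)
  # self-energy is a function of lp only: evaluate once per unique occupancy
  ulp <- unique(lps)
  uval <- vapply(ulp, function(l) {
    if (l <= 0) return(0)
    image_self_energy(self_energy_params(l, system$tau_lin, el$kappa,
                                         system$d, el$gamma_eps, el$lB),
                      rel.tol = rel.tol)
  }, numeric(1))
  out <- uval[match(lps, ulp)]
  if (system$sigma_m > 0) out <- out + mf_interaction_potential(system, zp)
  out
}
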