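# Iso-flux tension propagation (IFTP) theory of driven translocation for
# long polymers, in the strong-stretching regime. The translocation
# coordinate s (segments on the trans side) obeys overdamped Brownian
# dynamics with an effective friction Gamma = R + eta_p (+ s for the
# end-pulled case), where the tension front R separates the mobile from the
# still-equilibrated part of the cis subchain. Everything is in the reduced
# units of the coarse-grained chain: lengths in segments, forces in kBT per
# segment, kBT = 1.

#' IFTP model parameters
#'
#' @param N0 chain contour length in segments (`>= 2`).
#' @param f driving force in reduced units (`> 0`); applied at the pore
#'   (pore-driven) or on the head monomer (end-pulled).
#' @param eta_p pore friction in reduced units (`>= 0`).
#' @param nu Flory exponent (0.588 for a 3D self-avoiding chain, 3/4 in 2D,
#'   1 for a rod).
#' @param gamma_prime surface exponent of the entropic force (about 0.69 in
#'   3D, 0.95 in 2D, 0.5 for ideal chains).
#' @param A_nu amplitude of the tension-front relation `R = A_nu N^nu`.
#' @param mode `"pore-driven"` or `"end-pulled"`.
#' @param chain `"flexible"` or `"stiff"` (rodlike: `R(N) = N`, tension
#'   propagation instantaneous).
#' @param entropic include the equilibrium entropic force
#'   `(1 - gamma_prime)[1/(N0 - s) - 1/s]` (negligible in the
#'   strong-stretching regime; default off).
#' @param noise include Gaussian thermal noise (Euler-Maruyama integration;
#'   requires a `seed`).
#' @param kT thermal energy in reduced units (noise variance `2 Gamma kT dt`).
#' @param dt time step of the stochastic integrator.
#' @param seed integer seed, mandatory when `noise = TRUE`.
#' @return an object of class `iftp_params`.
#' @export
iftp_params <- function(N0, f, eta_p, nu = 0.588, gamma_prime = 0.69,
                        A_nu = 1.15, mode = c("pore-driven", "end-pulled"),
                        chain = c("flexible", "stiff"), entropic = FALSE,
                        noise = FALSE, kT = 1, dt = 1e-3, seed = NULL) {
  mode <- match.arg(mode); chain <- match.arg(chain)
  if (N0 < 2) stop_domain("iftp_params: N0 must be >= 2")
  if (f <= 0) stop_domain("iftp_params: f must be positive")
  if (eta_p < 0) stop_domain("iftp_params: eta_p must be >= 0")
  if (!(nu > 0 && nu <= 1)) stop_domain("iftp_params: need 0 < nu <= 1")
  if (gamma_prime < 0 || gamma_prime > 1)
    stop_domain("iftp_params: need 0 <= gamma_prime <= 1")
  if (A_nu <= 0) stop_domain("iftp_params: A_nu must be positive")
  if (noise && is.null(seed))
    stop_domain("iftp_params: stochastic runs require a seed")
  structure(list(N0 = N0, f = f, eta_p = eta_p, nu = nu,
                 gamma_prime = gamma_prime, A_nu = A_nu, mode = mode,
                 chain = chain, entropic = entropic, noise = noise,
                 kT = kT, dt = dt, seed = seed),
            class = "iftp_params")
}

#' @export
print.iftp_params <- function(x, ...) {
  cat(sprintf("IFTP parameters: %s %s chain, N0 = %g, f = %g, eta_p = %g\n",
              x$mode, x$chain, x$N0, x$f, x$eta_p))
  cat(sprintf("  nu = %g, gamma' = %g, A_nu = %g, entropic %s, noise %s\n",
              x$nu, x$gamma_prime, x$A_nu,
              if (x$entropic) "on" else "off",
              if (x$noise) sprintf("on (seed %d, dt %g)", x$seed, x$dt) else "off"))
  invisible(x)
}

# entropic force term, clamped away from the chain ends
.entropic_force <- function(p, s) {
  if (!p$entropic) return(0)
  s <- min(max(s, 1), p$N0 - 1)
  (1 - p$gamma_prime) * (1 / (p$N0 - s) - 1 / s)
}

# B(R) = nu A^(1/nu) R^((nu-1)/nu); the TP front equation is
# dR/dt = B/(1-B) * phi, valid while B < 1
.front_B <- function(p, R) p$nu * p$A_nu^(1 / p$nu) * R^((p$nu - 1) / p$nu)

#' Solve the IFTP equations
#'
#' Integrates the coupled equations for the translocation coordinate, the
#' monomer flux and the tension front. Tension propagation (TP) runs from
#' the seeded front `R(0) = A_nu` (one tensed segment) until the tension
#' reaches the chain end (`R + s = N0`), after which the front shrinks with
#' the flux (post-propagation, PP) until `s = N0`. Deterministic runs use
#' an adaptive ODE integrator with event detection; stochastic runs use
#' fixed-step Euler-Maruyama with noise variance `2 Gamma kT dt`.
#'
#' @param params an [iftp_params()].
#' @param keep_trajectory store the full trajectory (needed for
#'   [waiting_time()] of deterministic runs).
#' @param n_out approximate number of stored trajectory points.
#' @param rtol,atol tolerances of the deterministic integrator.
#' @return an object of class `iftp_result`: `tau`, `tau_tp`, `tau_pp`
#'   (reduced time units), the `trajectory` data frame (`t`, `s`, `R`,
#'   `phi`, `Gamma`, `stage`) when kept, the input `params`, and for
#'   stochastic runs the waiting-time accumulator `wt_bins`.
#' @export
iftp_solve <- function(params, keep_trajectory = TRUE, n_out = 2000,
                       rtol = 1e-10, atol = 1e-10) {
  stopifnot(inherits(params, "iftp_params"))
  if (params$noise) .iftp_solve_em(params, keep_trajectory)
  else .iftp_solve_det(params, keep_trajectory, n_out, rtol, atol)
}

.gamma_of <- function(p, R, s) {
  R + p$eta_p + if (p$mode == "end-pulled" || p$chain == "stiff") s else 0
}

.deriv_tp <- function(p) function(t, y, parms) {
  s <- y[1]; R <- y[2]
  phi <- (p$f + .entropic_force(p, s)) / .gamma_of(p, R, s)
  B <- .front_B(p, R)
  if (B >= 1) stop("TP front denominator crossed zero")
  list(c(phi, B / (1 - B) * phi))
}

.deriv_pp <- function(p) function(t, y, parms) {
  s <- y[1]; R <- y[2]
  phi <- (p$f + .entropic_force(p, s)) / .gamma_of(p, R, s)
  list(c(phi, -phi))
}

.iftp_solve_det <- function(p, keep, n_out, rtol, atol) {
  tau_guess <- analytic_translocation_time(iftp_params(
    p$N0, p$f, p$eta_p, p$nu, p$gamma_prime, p$A_nu, p$mode,
    chain = p$chain))
  tmax <- 20 * tau_guess
  stiff <- p$chain == "stiff"
  if (!stiff && .front_B(p, p$A_nu) >= 1)
    stop_domain(paste("iftp_solve: initial front violates the TP denominator",
                      "positivity (nu * A_nu^(1/nu) * R^((nu-1)/nu) >= 1);",
                      "the strong-stretching front equation does not apply"))
  # pass 1: stage durations via event detection
  if (stiff) {
    t_tp <- 0
    y0 <- c(s = 0, R = p$N0)
  } else {
    out <- deSolve::lsodar(c(s = 0, R = p$A_nu), c(0, tmax), .deriv_tp(p),
                           rootfunc = function(t, y, parms) y[1] + y[2] - p$N0,
                           rtol = rtol, atol = atol)
    t_tp <- attr(out, "troot")
    if (is.null(t_tp) || length(t_tp) == 0)
      stop_domain("iftp_solve: TP stage did not reach the chain end")
    y0 <- c(s = unname(out[nrow(out), "s"]), R = unname(out[nrow(out), "R"]))
  }
  out <- deSolve::lsodar(y0, c(0, tmax), .deriv_pp(p),
                         rootfunc = function(t, y, parms) y[1] - p$N0,
                         rtol = rtol, atol = atol)
  t_pp <- attr(out, "troot")
  if (is.null(t_pp) || length(t_pp) == 0)
    stop_domain("iftp_solve: PP stage did not complete")
  res <- list(tau = t_tp + t_pp, tau_tp = t_tp, tau_pp = t_pp, params = p)
  if (keep) {
    # pass 2: dense output over the known stage windows
    traj <- list()
    if (!stiff) {
      tt <- seq(0, t_tp, length.out = max(16L, ceiling(n_out * t_tp / res$tau)))
      otp <- deSolve::ode(c(s = 0, R = p$A_nu), tt, .deriv_tp(p),
                          rtol = rtol, atol = atol)
      traj$tp <- data.frame(t = otp[, "time"], s = otp[, "s"], R = otp[, "R"],
                            stage = "TP")
      y0 <- c(s = unname(otp[nrow(otp), "s"]), R = unname(otp[nrow(otp), "R"]))
    }
    tt <- seq(0, t_pp, length.out = max(16L, ceiling(n_out * t_pp / res$tau)))
    opp <- deSolve::ode(y0, tt, .deriv_pp(p), rtol = rtol, atol = atol)
    traj$pp <- data.frame(t = t_tp + opp[, "time"], s = opp[, "s"],
                          R = opp[, "R"], stage = "PP")
    tr <- do.call(rbind, traj)
    tr$s <- pmin(tr$s, p$N0)
    tr$phi <- (p$f + vapply(tr$s, function(s) .entropic_force(p, s),
                            numeric(1))) / .gamma_of(p, tr$R, tr$s)
    tr$Gamma <- .gamma_of(p, tr$R, tr$s)
    rownames(tr) <- NULL
    res$trajectory <- tr[order(tr$t), c("t", "s", "R", "phi", "Gamma", "stage")]
  }
  class(res) <- "iftp_result"
  res
}

# Fixed-step Euler-Maruyama on the same TP/PP equations as the
# deterministic solver. The front is clamped at its seeded value A_nu
# (at least one tensed segment); since B(R) decreases with R for nu < 1
# and nu * A_nu < 1 at the seed, the TP denominator stays positive for
# any noise realization.
.iftp_solve_em <- function(p, keep) {
  set.seed(p$seed)
  dt <- p$dt; sq <- sqrt(2 * p$kT * dt)
  stage <- if (p$chain == "stiff") "PP" else "TP"
  s <- 0
  R <- if (p$chain == "stiff") p$N0 else p$A_nu
  if (p$chain != "stiff" && .front_B(p, p$A_nu) >= 1)
    stop_domain("iftp_solve: initial front violates the TP denominator positivity")
  t <- 0; t_tp <- if (p$chain == "stiff") 0 else NA_real_
  wt <- numeric(p$N0)
  keep_every <- max(1L, floor(p$N0 / dt / 2e4))
  rows <- list(); i <- 0L
  repeat {
    i <- i + 1L
    Gam <- .gamma_of(p, R, s)
    ds <- (p$f + .entropic_force(p, s)) / Gam * dt +
      sq / sqrt(Gam) * stats::rnorm(1)
    bin <- min(p$N0, floor(s) + 1L)
    wt[bin] <- wt[bin] + dt
    if (stage == "TP") {
      B <- .front_B(p, R)
      R <- max(R + B / (1 - B) * ds, p$A_nu)
    } else {
      R <- max(R - ds, 0)
    }
    s <- s + ds
    if (s < 0) s <- -s                         # reflect at the entrance
    t <- t + dt
    if (stage == "TP" && R + s >= p$N0) { stage <- "PP"; t_tp <- t }
    if (keep && i %% keep_every == 0L)
      rows[[length(rows) + 1L]] <- c(t, s, R, stage == "TP")
    if (s >= p$N0) break
    if (i > 1e9) stop_domain("iftp_solve: stochastic run did not terminate")
  }
  res <- list(tau = t, tau_tp = t_tp, tau_pp = t - t_tp, params = p,
              wt_bins = wt)
  if (keep && length(rows)) {
    m <- do.call(rbind, rows)
    res$trajectory <- data.frame(t = m[, 1], s = m[, 2], R = m[, 3],
                                 phi = NA_real_, Gamma = NA_real_,
                                 stage = ifelse(m[, 4] == 1, "TP", "PP"))
  }
  class(res) <- "iftp_result"
  res
}

#' @export
print.iftp_result <- function(x, ...) {
  cat(sprintf("IFTP solution (%s, %s): tau = %.6g (TP %.6g + PP %.6g)\n",
              x$params$mode, x$params$chain, x$tau, x$tau_tp, x$tau_pp))
  invisible(x)
}

#' @export
plot.iftp_result <- function(x, ...) {
  if (is.null(x$trajectory)) stop_domain("plot.iftp_result: no trajectory stored")
  with(x$trajectory, {
    plot(t, s, type = "l", xlab = "t (reduced)", ylab = "s, R (segments)", ...)
    graphics::lines(t, R, lty = 2)
    graphics::legend("topleft", c("s", "R"), lty = 1:2, bty = "n")
  })
  invisible(x)
}

#' Waiting-time profile
#'
#' Time the chain spends at each value of the translocation coordinate:
#' `w(k)` is the time during which `s` lies in `[k - 1, k)`. For a
#' deterministic solution the monotone trajectory is inverted; stochastic
#' solutions return the per-bin time accumulated during integration.
#'
#' @param result an [iftp_result()] with a stored trajectory.
#' @return data frame with columns `s_bin` (`1..N0`) and `w` (reduced time).
#' @export
waiting_time <- function(result) {
  stopifnot(inherits(result, "iftp_result"))
  N0 <- result$params$N0
  if (!is.null(result$wt_bins))
    return(data.frame(s_bin = seq_len(N0), w = result$wt_bins))
  tr <- result$trajectory
  if (is.null(tr)) stop_domain("waiting_time: solve with keep_trajectory = TRUE")
  # deterministic s(t) is strictly increasing: invert by interpolation
  keep <- !duplicated(tr$s)
  tcross <- stats::approx(tr$s[keep], tr$t[keep], xout = 0:N0, rule = 2)$y
  tcross[N0 + 1] <- result$tau
  data.frame(s_bin = seq_len(N0), w = diff(tcross))
}

#' Closed-form strong-stretching translocation times
#'
#' The analytic reduced translocation time with the total force
#' approximated by the bare driving force:
#' pore-driven `tau = [A_nu N0^(1+nu)/(1+nu) + eta_p N0] / f`; end-pulled
#' adds the straightened trans-side term `N0^2/2` inside the bracket; a
#' stiff (rodlike) chain gives `tau = (eta_p N0 + N0^2) / f`.
#'
#' @param params an [iftp_params()].
#' @return reduced translocation time.
#' @export
analytic_translocation_time <- function(params) {
  stopifnot(inherits(params, "iftp_params"))
  with(params, {
    if (chain == "stiff") return((eta_p * N0 + N0^2) / f)
    cis <- A_nu * N0^(1 + nu) / (1 + nu) + eta_p * N0
    if (mode == "end-pulled") (cis + N0^2 / 2) / f else cis / f
  })
}

#' Log-log scaling exponent of the translocation time
#'
#' Least-squares slope of `log(tau_rescaled)` against `log(N0)`. Rescaling
#' modes: `"none"` (the bare effective exponent alpha), `"pore-friction"`
#' (subtract `eta_p N0 / f`; isolates the cis-side friction contribution,
#' exponent `1 + nu`), `"trans-side"` (subtract the cis and pore terms
#' `[int_0^N0 A_nu N^nu dN + eta_p N0] / f`; isolates the straightened
#' trans-side friction of end-pulled translocation, exponent 2).
#'
#' @param N0 chain lengths (>= 4 values for a fit).
#' @param tau corresponding translocation times.
#' @param rescale one of `"none"`, `"pore-friction"`, `"trans-side"`.
#' @param f,eta_p,A_nu,nu parameters used by the rescaling definitions.
#' @param window optional `c(min, max)` range of `N0` used in the fit.
#' @return object of class `iftp_scaling`: `exponent`, `prefactor`, the
#'   fitted `data`, `rescale`, `window`. `coef()` returns the exponent.
#' @export
scaling_exponent <- function(N0, tau, rescale = c("none", "pore-friction",
                                                  "trans-side"),
                             f = NULL, eta_p = NULL, A_nu = 1.15, nu = 0.588,
                             window = NULL) {
  rescale <- match.arg(rescale)
  if (length(N0) < 4 || length(tau) != length(N0))
    stop_domain("scaling_exponent: need >= 4 matching (N0, tau) points")
  tau_r <- switch(rescale,
    none = tau,
    "pore-friction" = tau - eta_p * N0 / f,
    "trans-side" = tau - (A_nu * N0^(1 + nu) / (1 + nu) + eta_p * N0) / f)
  if (any(tau_r <= 0))
    stop_domain("scaling_exponent: nonpositive rescaled times at N0 = %s",
                paste(N0[tau_r <= 0], collapse = ", "))
  use <- if (is.null(window)) rep(TRUE, length(N0))
         else N0 >= window[1] & N0 <= window[2]
  fit <- stats::lm(log(tau_r[use]) ~ log(N0[use]))
  out <- list(exponent = unname(stats::coef(fit)[2]),
              prefactor = exp(unname(stats::coef(fit)[1])),
              data = data.frame(N0 = N0, tau = tau, tau_rescaled = tau_r),
              rescale = rescale, window = window)
  class(out) <- "iftp_scaling"
  out
}

#' Translocation-time scaling sweep
#'
#' Solves the deterministic IFTP equations over a grid of chain lengths and
#' fits the scaling exponent of the (optionally rescaled) translocation
#' time.
#'
#' @param N0 vector of chain lengths.
#' @param f,eta_p,A_nu,nu,mode,chain model parameters (see [iftp_params()]).
#' @param rescale,window passed to [scaling_exponent()].
#' @return an `iftp_scaling` object (see [scaling_exponent()]).
#' @examples
#' fit <- iftp_scaling(2^(7:11), f = 5, eta_p = 5, rescale = "pore-friction")
#' coef(fit)  # ~ 1 + nu
#' @export
iftp_scaling <- function(N0, f, eta_p, A_nu = 1.15, nu = 0.588,
                         mode = "pore-driven", chain = "flexible",
                         rescale = "none", window = NULL) {
  tau <- vapply(N0, function(n) {
    iftp_solve(iftp_params(n, f, eta_p, nu = nu, A_nu = A_nu, mode = mode,
                           chain = chain),
               keep_trajectory = FALSE)$tau
  }, numeric(1))
  scaling_exponent(N0, tau, rescale = rescale, f = f, eta_p = eta_p,
                   A_nu = A_nu, nu = nu, window = window)
}

#' @export
print.iftp_scaling <- function(x, ...) {
  cat(sprintf("IFTP scaling fit (%s rescaling): exponent = %.6f over %d points\n",
              x$rescale, x$exponent, nrow(x$data)))
  invisible(x)
}

#' @export
coef.iftp_scaling <- function(object, ...) {
  c(exponent = object$exponent, prefactor = object$prefactor)
}

#' @export
plot.iftp_scaling <- function(x, ...) {
  plot(x$data$N0, x$data$tau_rescaled, log = "xy", xlab = "N0",
       ylab = "rescaled tau", ...)
  invisible(x)
}
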