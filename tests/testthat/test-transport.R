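# Steady-state Smoluchowski transport: occupancy, effective potential,
# capture rate, translocation time, density profile, mean velocity.

flat_pot <- function(D = 2, zex_Lm = 6, zex_Lp = 9, vdr = 0) {
  # hand-built effective potential object for closed-form checks
  g <- occupancy_geometry(zex_Lm, zex_Lp)
  structure(list(beta_Up = function(z) -vdr / D * z,
                 Vp = function(z) rep(0, length(z)),
                 lambda_d = vdr / D, lambda_b = 0, D = D, Dpa = D / 2,
                 vdr = vdr, geom = g, zex = g$zex, barrier = "none"),
            class = "effective_potential")
}

test_that("pore occupancy is piecewise linear, continuous and bounded", {
  g <- occupancy_geometry(5, 10)
  expect_equal(g$Lminus, 5); expect_equal(g$Lplus, 10); expect_equal(g$zex, 15)
  expect_equal(pore_occupancy(g, 0), 0)
  expect_equal(pore_occupancy(g, 15), 0)
  expect_equal(pore_occupancy(g, 7), 5)          # plateau
  expect_equal(pore_occupancy(g, 3), 3)          # capture branch
  expect_equal(pore_occupancy(g, 12), 3)         # escape branch
  eps <- 1e-12
  expect_equal(pore_occupancy(g, 5 - eps), pore_occupancy(g, 5 + eps),
               tolerance = 1e-9)
  expect_equal(pore_occupancy(g, 10 - eps), pore_occupancy(g, 10 + eps),
               tolerance = 1e-9)
  # swapped roles of Lm and Lp give the same occupancy
  expect_equal(pore_occupancy(occupancy_geometry(10, 5), 7), 5)
  expect_error(pore_occupancy(g, 16), "zex")
})

test_that("flat potential gives the closed-form rate, time and profile", {
  pot <- flat_pot(D = 2)
  zex <- pot$zex
  expect_equal(capture_rate(pot), pot$D / zex, tolerance = 1e-10)
  tt <- translocation_time(pot)
  expect_equal(tt$tau, zex^2 / (2 * pot$D), tolerance = 1e-10)
  dp <- density_profile(pot)
  expect_equal(dp$profile$c_over_ccis,
               1 - dp$profile$zp_nm / zex, tolerance = 1e-10)
  expect_equal(dp$N, zex / 2, tolerance = 1e-6)
  expect_equal(mean_velocity(pot), 0, tolerance = 1e-10)
})

test_that("pure-drift capture rate reproduces the closed identity for both
           signs of the drift", {
  for (vdr in c(8, -8, 0.3, -0.3)) {
    pot <- flat_pot(D = 2, vdr = vdr)
    expect_equal(capture_rate(pot),
                 vdr / (1 - exp(-vdr * pot$zex / pot$D)),
                 tolerance = 1e-8)
  }
  # strong positive drift: Rc -> vdr
  pot <- flat_pot(D = 1, vdr = 50)
  expect_equal(capture_rate(pot), 50, tolerance = 1e-8)
})

test_that("capture rate agrees with a brute-force Riemann oracle on an
           arbitrary smooth potential", {
  g <- occupancy_geometry(6, 9)
  u <- function(z) 3 * sin(z) + 0.2 * z
  pot <- structure(list(beta_Up = u, Vp = function(z) 0, lambda_d = 0,
                        lambda_b = 0, D = 2, Dpa = 1, vdr = 0, geom = g,
                        zex = g$zex, barrier = "custom"),
                   class = "effective_potential")
  oracle <- 2 / riemann_boltzmann(u, g$zex, n = 1e6)
  expect_equal(capture_rate(pot, n = 20001), oracle, tolerance = 1e-6)
})

test_that("observables are invariant under a constant potential shift and Rc
           decreases when the potential is raised", {
  g <- occupancy_geometry(6, 9)
  mk <- function(c0, amp = 1.5) structure(
    list(beta_Up = function(z) amp * sin(z / 2) + c0, Vp = function(z) 0,
         lambda_d = 0, lambda_b = 0, D = 2, Dpa = 1, vdr = 0, geom = g,
         zex = g$zex, barrier = "custom"),
    class = "effective_potential")
  p0 <- mk(0); p5 <- mk(5)
  expect_equal(capture_rate(p0), capture_rate(p5), tolerance = 1e-10)
  expect_equal(translocation_time(p0)$tau, translocation_time(p5)$tau,
               tolerance = 1e-10)
  expect_equal(mean_velocity(p0), mean_velocity(p5), tolerance = 1e-10)
  expect_equal(density_profile(p0)$profile$c_over_ccis,
               density_profile(p5)$profile$c_over_ccis, tolerance = 1e-10)
  # pointwise-higher interior potential lowers the capture rate
  raised <- structure(list(beta_Up = function(z) 1.5 * sin(z / 2) +
                             2 * sin(pi * z / g$zex)^2,
                           Vp = function(z) 0, lambda_d = 0, lambda_b = 0,
                           D = 2, Dpa = 1, vdr = 0, geom = g, zex = g$zex,
                           barrier = "custom"),
                      class = "effective_potential")
  expect_lt(capture_rate(raised), capture_rate(p0))
})

test_that("translocation-time components partition the double integral", {
  sys <- solidstate_system()
  pot <- effective_potential(sys)
  tt <- translocation_time(pot)
  expect_equal(tt$tau, tt$tau1 + tt$tau2 + tt$tau3, tolerance = 1e-12)
  expect_true(all(c(tt$tau1, tt$tau2, tt$tau3) > 0))
  # strong drift: tau ~ zex / vdr
  pot2 <- flat_pot(D = 1, vdr = 4)  # vdr*zex/D = 60 > 50
  tt2 <- translocation_time(pot2)
  expect_equal(tt2$tau, pot2$zex / pot2$vdr, tolerance = 0.05)
})

test_that("density profile has the reservoir and absorbing boundaries and a
           uniform steady flux", {
  sys <- solidstate_system()
  pot <- effective_potential(sys)
  dp <- density_profile(pot, ccis = 1)
  pr <- dp$profile
  expect_equal(pr$c_over_ccis[1], 1, tolerance = 1e-12)
  expect_equal(pr$c_over_ccis[nrow(pr)], 0, tolerance = 1e-12)
  # J = -D c' + vp c constant: evaluate at interior points by numerical
  # differentiation of the stored profile
  z <- pr$zp_nm; conc <- pr$c_over_ccis
  i <- round(seq(0.15, 0.85, length.out = 5) * nrow(pr))
  dcdz <- (conc[i + 1] - conc[i - 1]) / (z[i + 1] - z[i - 1])
  vp <- pr$vp_nm_per_us[i] * 1e6
  J <- -pot$D * dcdz + vp * conc[i]
  expect_lt(diff(range(J)) / abs(mean(J)), 1e-5)
  expect_equal(mean(J), dp$Jst, tolerance = 1e-4)
})

test_that("mean velocity matches the drift for flat interactions, the
           lambda difference in both regimes, and the flux identity", {
  pot <- flat_pot(D = 2, vdr = 7)
  expect_equal(mean_velocity(pot), 7, tolerance = 1e-10)
  # drift-dominated and barrier-dominated mean-field systems
  drift <- effective_potential(solidstate_system())         # lambda_d >> lambda_b
  expect_gt(drift$lambda_d, 10 * abs(drift$lambda_b))
  expect_equal(mean_velocity(drift), drift$D * (drift$lambda_d - drift$lambda_b),
               tolerance = 0.1)
  barrier <- effective_potential(
    solidstate_system(rho_b = 0.05, dV = 0.003, dP = 0))   # lambda_b >> lambda_d
  expect_gt(barrier$lambda_b, 5 * barrier$lambda_d)
  expect_equal(mean_velocity(barrier),
               barrier$D * (barrier$lambda_d - barrier$lambda_b),
               tolerance = 0.1)
  # steady-state identity: int vp c = Jst zex - D ccis (independent of the
  # quadrature used for the mean)
  dp <- density_profile(drift)
  lhs <- mean_velocity(drift) * dp$N
  expect_equal(lhs, dp$Jst * drift$zex - drift$D, tolerance = 1e-4)
})

test_that("mean-field effective potential reduces to the inverse-length form", {
  sys <- solidstate_system()
  pot <- effective_potential(sys)
  g <- pot$geom
  # beta Up(Lminus) - beta Up(0) = (lambda_b - lambda_d) Lminus
  expect_equal(pot$beta_Up(g$Lminus) - pot$beta_Up(0),
               (pot$lambda_b - pot$lambda_d) * g$Lminus, tolerance = 1e-9)
  expect_gt(pot$lambda_b, 0)     # like-charged surfaces
  # no interaction: linear potential with slope -lambda_d
  pot0 <- effective_potential(sys, barrier = "none")
  z <- seq(0, g$zex, length.out = 7)
  expect_equal(pot0$beta_Up(z), -pot0$lambda_d * z, tolerance = 1e-12)
})
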