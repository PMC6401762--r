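# Debye-Hueckel annular electrostatics, membrane potential, mean-field
# interaction and cumulative charge.

test_that("Bjerrum length matches direct evaluation and scales as 1/eps_w", {
  # independent arithmetic with CODATA constants
  kB <- 1.380649e-23; e <- 1.602176634e-19; eps0 <- 8.8541878128e-12
  expect_equal(bjerrum_length(298.15, 80),
               e^2 / (4 * pi * eps0 * 80 * kB * 298.15) * 1e9,
               tolerance = 1e-12)
  expect_equal(bjerrum_length(298.15, 80), 0.70, tolerance = 0.01)
  expect_equal(bjerrum_length(300, 40), 2 * bjerrum_length(300, 80),
               tolerance = 1e-12)
  expect_lt(bjerrum_length(298.15, 1e9), 1e-7)
  expect_error(bjerrum_length(-1, 80), "positive")
  expect_error(bjerrum_length(300, 0), "positive")
})

test_that("Debye parameter reproduces the monovalent-salt screening length", {
  # lambda_D ~ 0.304 nm / sqrt(c[M]) for 1:1 salt at room temperature
  for (c in c(0.01, 0.1, 1)) {
    el <- electrolyte(rho_b = c)
    expect_equal(1 / el$kappa, 0.304 / sqrt(c), tolerance = 0.02)
  }
  expect_equal(electrolyte(0)$kappa, 0)
  expect_equal(electrolyte(0.2)$kappa, sqrt(2) * electrolyte(0.1)$kappa,
               tolerance = 1e-12)
  # general valency form: 2:1 salt ionic strength
  el21 <- electrolyte(species = data.frame(valency = c(2, -1),
                                           conc_M = c(0.1, 0.2)))
  el11 <- electrolyte(rho_b = 0.1)
  expect_equal(el21$kappa / el11$kappa, sqrt((4 * 0.1 + 0.2) / 0.2),
               tolerance = 1e-12)
  expect_error(electrolyte(rho_b = -0.1), "non-negative")
  expect_error(electrolyte(species = data.frame(valency = c(1, -1),
                                                conc_M = c(0.2, 0.1))),
               "electroneutral")
})

test_that("annular DH solver satisfies both Gauss conditions exactly", {
  for (p in list(c(1, 5, 0.1, 0.4, 0.13), c(0.5, 0.85, 0.04, 2.9 / pi, 0),
                 c(2, 6, 1.0, 0.1, 0.4))) {
    sys <- pore_system(a = p[1], d = p[2], Lm = 10, Lp = 20,
                       sigma_p = p[4], sigma_m = p[5],
                       electrolyte = electrolyte(p[3]))
    f <- dh_annulus_potential(sys)
    lB <- sys$electrolyte$lB
    scale <- max(4 * pi * lB * max(p[4], p[5]), 1e-12)
    expect_lt(abs(f$dphi_at(p[1]) - 4 * pi * lB * p[4]) / scale, 1e-8)
    expect_lt(abs(f$dphi_at(p[2]) + 4 * pi * lB * p[5]) / scale, 1e-8)
  }
})

test_that("annular DH solver agrees with a finite-difference BVP oracle", {
  sys <- solidstate_system()
  f <- dh_annulus_potential(sys)
  lB <- sys$electrolyte$lB; kap <- sys$electrolyte$kappa
  o <- fd_annulus_oracle(sys$a, sys$d, kap,
                         ga = 4 * pi * lB * sys$sigma_p,
                         gd = -4 * pi * lB * sys$sigma_m)
  expect_lt(max(abs(f$phi_at(o$r) - o$phi)) / max(abs(o$phi)), 1e-5)
})

test_that("zero charges give the zero field; output is additive in charges", {
  sys0 <- pore_system(a = 1, d = 4, Lm = 10, Lp = 20, sigma_p = 0,
                      sigma_m = 0, electrolyte = electrolyte(0.1))
  expect_true(all(dh_annulus_potential(sys0)$phi == 0))
  # additivity (linearity of the screened equation)
  mk <- function(sp, sm) dh_annulus_potential(
    pore_system(a = 1, d = 4, Lm = 10, Lp = 20, sigma_p = sp, sigma_m = sm,
                electrolyte = electrolyte(0.1)))
  r <- seq(1, 4, length.out = 41)
  both <- mk(0.3, 0.2); pol <- mk(0.3, 0); mem <- mk(0, 0.2)
  expect_equal(both$phi_at(r), pol$phi_at(r) + mem$phi_at(r),
               tolerance = 1e-12)
})

test_that("wide neutral-wall annulus approaches the isolated charged cylinder", {
  kap <- 0.5; a <- 1; sp <- 0.4
  sys <- pore_system(a = a, d = 50 / kap, Lm = 10, Lp = 20, sigma_p = sp,
                     sigma_m = 0,
                     electrolyte = electrolyte(nm3_to_molar(kap^2 /
                                                (8 * pi * bjerrum_length()))))
  f <- dh_annulus_potential(sys)
  lB <- sys$electrolyte$lB
  iso <- function(r) -4 * pi * lB * sp * besselK(kap * r, 0) /
    (kap * besselK(kap * a, 1))
  r <- c(1, 2, 5, 10)
  expect_equal(f$phi_at(r), iso(r), tolerance = 1e-8)
})

test_that("kappa = 0 with surface charges is rejected; geometry errors named", {
  expect_error(dh_annulus_potential(
    pore_system(a = 1, d = 4, Lm = 10, Lp = 20, sigma_p = 0.1, sigma_m = 0,
                electrolyte = electrolyte(0))), "screened")
  expect_error(pore_system(a = 4, d = 4, Lm = 10, Lp = 20, sigma_p = 0,
                           sigma_m = 0), "'a'")
})

test_that("membrane potential is the polymer-free limit and is negative", {
  sys <- solidstate_system()
  pm <- membrane_potential(sys)
  direct <- dh_annulus_potential(
    pore_system(a = sys$a, d = sys$d, Lm = sys$Lm, Lp = sys$Lp,
                sigma_p = 0, sigma_m = sys$sigma_m, dV = sys$dV,
                dP = sys$dP, electrolyte = sys$electrolyte))
  r <- seq(sys$a, sys$d, length.out = 31)
  expect_equal(pm$phi_at(r), direct$phi_at(r), tolerance = 1e-14)
  expect_true(all(pm$phi_at(r) < 0))         # anionic membrane
  expect_lt(abs(pm$dphi_at(sys$a)), 1e-10)   # regular at the polymer surface
  sysn <- pore_system(a = 1, d = 4, Lm = 10, Lp = 20, sigma_p = 0.3,
                      sigma_m = 0, electrolyte = electrolyte(0.1))
  expect_true(all(membrane_potential(sysn)$phi == 0))
})

test_that("mean-field interaction is repulsive, plateaued and linear in charges", {
  sys <- pore_system(a = 1, d = 4, Lm = 5, Lp = 10, sigma_p = 0.3,
                     sigma_m = 0.2, electrolyte = electrolyte(0.1))
  zp <- seq(0, sys$zex, length.out = 61)
  v <- mf_interaction_potential(sys, zp)
  expect_true(all(v >= 0))                       # like-charge repulsion
  plateau <- v[zp >= sys$Lminus & zp <= sys$Lplus]
  expect_lt(diff(range(plateau)), 1e-10 * max(v))
  # linear in sigma_p at fixed membrane potential
  pm <- membrane_potential(sys)
  sys2 <- pore_system(a = 1, d = 4, Lm = 5, Lp = 10, sigma_p = 0.6,
                      sigma_m = 0.2, electrolyte = electrolyte(0.1))
  expect_equal(mf_interaction_potential(sys2, zp, phi_m = pm), 2 * v,
               tolerance = 1e-12)
  expect_equal(mf_interaction_potential(
    pore_system(a = 1, d = 4, Lm = 5, Lp = 10, sigma_p = 0.3, sigma_m = 0,
                electrolyte = electrolyte(0.1)), zp), rep(0, length(zp)))
  expect_error(mf_interaction_potential(sys, sys$zex + 1), "zex")
})

test_that("cumulative charge starts at the bare polymer charge and closes", {
  sys <- pore_system(a = 1, d = 8, Lm = 10, Lp = 20, sigma_p = 0.3,
                     sigma_m = 0, electrolyte = electrolyte(0.1))
  f <- dh_annulus_potential(sys)
  expect_equal(cumulative_charge(sys, f, sys$a), -2 * pi * sys$a * sys$sigma_p)
  # neutral wall: global electroneutrality, for several salt densities
  for (c in c(0.05, 0.1, 0.5)) {
    sc <- pore_system(a = 1, d = 8, Lm = 10, Lp = 20, sigma_p = 0.3,
                      sigma_m = 0, electrolyte = electrolyte(c))
    fc <- dh_annulus_potential(sc)
    expect_lt(abs(cumulative_charge(sc, fc, sc$d)) /
                (2 * pi * sc$a * sc$sigma_p), 1e-6)
  }
  # Gauss-law identity oracle: Qcum(r) = -r phi'(r) / (2 lB)
  r <- c(1.5, 2, 4, 6)
  expect_equal(cumulative_charge(sys, f, r),
               -r * f$dphi_at(r) / (2 * sys$electrolyte$lB),
               tolerance = 1e-6)
  # counterion screening: monotone increase away from the polymer
  q <- cumulative_charge(sys, f, seq(1, 8, length.out = 30))
  expect_true(all(diff(q) > 0))
  expect_error(cumulative_charge(sys, f, 0.5), "outside")
})
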