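# Independent numerical oracles used across the test files.

# Finite-difference two-point boundary-value solve of the linearized radial
# equation  phi'' + phi'/r - kappa^2 phi = 0  with Neumann conditions
# phi'(a) = ga, phi'(d) = gd (ghost-node discretization, Thomas algorithm).
fd_annulus_oracle <- function(a, d, kappa, ga, gd, n = 8001) {
  r <- seq(a, d, length.out = n)
  h <- r[2] - r[1]
  lo <- numeric(n); di <- numeric(n); up <- numeric(n); rhs <- numeric(n)
  i <- 2:(n - 1)
  lo[i] <- 1 / h^2 - 1 / (2 * r[i] * h)
  di[i] <- -2 / h^2 - kappa^2
  up[i] <- 1 / h^2 + 1 / (2 * r[i] * h)
  # ghost nodes: phi0 = phi2 - 2h*ga, phi_{n+1} = phi_{n-1} + 2h*gd
  di[1] <- -2 / h^2 - kappa^2; up[1] <- 2 / h^2
  rhs[1] <- (2 / h - 1 / r[1]) * ga
  di[n] <- -2 / h^2 - kappa^2; lo[n] <- 2 / h^2
  rhs[n] <- -(2 / h + 1 / r[n]) * gd
  # Thomas algorithm
  cp <- numeric(n); dp <- numeric(n)
  cp[1] <- up[1] / di[1]; dp[1] <- rhs[1] / di[1]
  for (k in 2:n) {
    m <- di[k] - lo[k] * cp[k - 1]
    cp[k] <- up[k] / m
    dp[k] <- (rhs[k] - lo[k] * dp[k - 1]) / m
  }
  phi <- numeric(n); phi[n] <- dp[n]
  for (k in (n - 1):1) phi[k] <- dp[k] - cp[k] * phi[k + 1]
  list(r = r, phi = phi)
}

# midpoint Riemann sum of int_0^zex exp(u(z) - u(0)) dz
riemann_boltzmann <- function(u, zex, n = 1e6) {
  z <- (seq_len(n) - 0.5) * zex / n
  mean(exp(u(z) - u(0))) * zex
}

# standard test systems
alphahl_system <- function(rho_b = 0.04, dV = 0.12) {
  pore_system(a = 0.5, d = 0.85, Lm = 5, Lp = 10,
              sigma_p = 2.9 / pi, sigma_m = 0, dV = dV,
              electrolyte = electrolyte(rho_b))
}

solidstate_system <- function(rho_b = 1.6, dV = -0.1, dP = atm_to_pa(2)) {
  pore_system(a = 1, d = 5, Lm = 200, Lp = 180, sigma_p = 0.4,
              sigma_m = 0.13, dV = dV, dP = dP,
              electrolyte = electrolyte(rho_b))
}
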