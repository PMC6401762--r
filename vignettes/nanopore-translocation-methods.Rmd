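---
title: "Methods: electrohydrodynamics and tension propagation of driven polymer translocation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: electrohydrodynamics and tension propagation of driven polymer translocation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nanotransloc)
```

Driven polymer translocation — a DNA or RNA molecule pulled through a
nanometre-scale pore by a voltage or a pressure gradient — separates into two
tractable regimes. When the polymer is no longer than the pore
(tens of nanometres, below the DNA persistence length), conformational
fluctuations are negligible and the physics is carried by the pore
*electrohydrodynamics*: screened electrostatics, electroosmosis and streaming
flow acting on a rigid rod. When the polymer is much longer than the pore,
the pore details collapse into an effective driving force and pore friction,
and the physics is carried by the *non-equilibrium conformational response*
of the chain — tension propagating along the backbone. `nanotransloc`
implements one engine for each regime. This vignette records the models, the
numerical choices, and the design decisions that were genuinely open.

## 1. The electrohydrodynamic engine (short, stiff polymers)

### 1.1 Geometry and fields

A rigid cylindrical polymer (radius $a$, contour length $L_p$, surface charge
magnitude $\sigma_p$, stored positive and applied as anionic) sits on the axis
of a cylindrical pore (radius $d$, membrane thickness $L_m$, wall charge
magnitude $\sigma_m$). The reaction coordinate $z_p \in [0, z_{ex}]$,
$z_{ex} = L_p + L_m$, is the position of the polymer's leading end; the
in-pore length $l_p(z_p)$ is the piecewise-linear occupancy (capture ramp,
plateau at $L_- = \min(L_m, L_p)$, escape ramp).

The dimensionless electrostatic potential $\phi(r)$ (thermal units $k_BT/e$)
solves the linearized Poisson–Boltzmann equation in the annulus
$a \le r \le d$,
$$\frac{1}{r}\,\partial_r\, r\, \partial_r \phi = \kappa^2 \phi , \qquad
  \phi'(a) = 4\pi \ell_B \sigma_p, \quad \phi'(d) = -4\pi \ell_B \sigma_m,$$
with $\ell_B$ the Bjerrum length and $\kappa$ the Debye–Hückel screening
parameter of the electrolyte. The solution is the modified-Bessel combination
$c_1 I_0(\kappa r) + c_2 K_0(\kappa r)$ with the constants fixed by the two
Gauss conditions. Numerically the two basis functions are normalized to
$I_0(\kappa r)/I_0(\kappa d)$ and $K_0(\kappa r)/K_0(\kappa a)$ and evaluated
through exponentially scaled Bessel functions, so the solver never overflows
at large $\kappa d$ (tested up to $\kappa d \sim 10^2$). With $\kappa = 0$
and nonzero surface charges the two Neumann conditions are inconsistent
(Gauss' law fixes the total enclosed charge), so that case is an error
rather than a silent logarithmic fallback; the zero-charge case returns the
zero field.

The membrane-only potential $\phi_m$ is the same solve with $\sigma_p = 0$,
and the mean-field polymer–membrane interaction is
$V_p(z_p) = -2\pi a \sigma_p\, \phi_m(a)\, l_p(z_p)\, k_BT$ — a repulsive
barrier for two anionic surfaces, linear in the in-pore length.

### 1.2 Hydrodynamics

The Stokes equation in the annulus, with no-slip at the wall and at the
polymer surface, gives the drift velocity
$$v_{dr} = \mu_e \frac{\Delta V}{L_m}\left[\phi(d) - \phi(a)\right]
  + \frac{\gamma a^2 \Delta P}{4 \eta L_m}, \qquad
  \gamma = \frac{d^2}{a^2} - 1 - 2\ln\frac{d}{a},$$
with $\mu_e = \varepsilon_0 \varepsilon_w k_BT/(e\eta)$ the electrophoretic
mobility coefficient. The first bracket contains electrophoresis and the
opposing electroosmotic drag; the second term is the streaming-flow
contribution. Sign conventions: $\Delta V = V_{trans} - V_{cis}$,
$\Delta P = P_{cis} - P_{trans}$, and all velocities are positive for
cis$\to$trans motion. The full fluid profile and the two diffusion
coefficients, $D = k_BT \ln(L_p/2a)/(3\pi\eta L_p)$ (bulk rod) and
$D_p(r) = k_BT\ln(d/r)/(2\pi\eta L_p)$ (pore medium), share one helper;
$L_p \le 2a$ is rejected because the log would make $D$ non-positive.

### 1.3 Smoluchowski transport

The translocation coordinate obeys steady-state drift–diffusion with the
reservoir condition $c(0) = c_{cis}$ and an absorbing exit $c(z_{ex}) = 0$,
under the effective potential
$$\beta U_p(z_p) = \frac{D_p(a)}{D}\,\beta V_p(z_p) - \frac{v_{dr}}{D} z_p
 \;=\; \lambda_b\, l_p(z_p) - \lambda_d\, z_p \quad \text{(mean-field form)}.$$
The capture rate, mean first-passage time (split into capture, plateau and
escape parts), density profile and density-weighted mean velocity are
Boltzmann integrals of $U_p$.

**Quadrature.** Rather than generic adaptive quadrature, the potential is
tabulated on a grid with knots forced at the occupancy kinks $L_\pm$ and
interpolated piecewise-linearly; every segment integral of
$e^{\pm\beta U_p}$ then has a closed form. This is *exact* for the
mean-field potential (which is piecewise linear) and for pure drift, and
reproduces a $10^6$-point Riemann sum to better than $10^{-6}$ relative on
smooth test potentials with a 20 001-point grid (default 2 001).

**Overflow policy.** $\beta U_p$ can exceed $\pm 100$ at biological-pore
parameters. All observables are computed under a global shift of
$\beta U_p$ (which cancels identically): a centered shift for the rate and
time (safe for potential ranges up to $\sim$1400 $k_BT$), and a max-shift
with log-domain density weights for the profile and the mean velocity, so
the trapping root searches never produce overflow `NaN`s even at extreme
pressures.

### 1.4 Image-charge barrier in biological pores

For a sub-nanometre pore through a low-permittivity membrane
($\varepsilon_m \approx 2 \ll \varepsilon_w = 80$) a neutral wall still
repels the polymer: the in-pore charge interacts with its dielectric image.
The self-energy of the in-pore portion is the Fourier integral
$$\beta\Delta\Omega_p(l_p) = l_p \ell_B \tau^2 \int_{-\infty}^{\infty}
  \frac{2\sin^2(q l_p/2)}{\pi l_p q^2}\, \Delta(q)\, dq,$$
with $\tau = 2\pi a \sigma_p$ the line charge density and $\Delta(q)$ the
dielectric jump function (a ratio of modified Bessel functions of
$p_b d$ and $|q| d$, $p_b = \sqrt{\kappa^2 + q^2}$). The integrand is even,
finite at $q = 0$ (limit $l_p^2 \Delta(0)/4$ with
$\Delta(0) = K_1(\kappa d)/I_1(\kappa d)$), and integrated adaptively on
$[0, q_{max}]$ with $q_{max} = \max(40/d,\, 20\kappa)$ at $10^{-8}$
relative tolerance; large-argument Bessel products use scaled evaluations
with the exponents combined analytically. In strong salt the integral
approaches $\pi \ell_B l_p \tau^2 e^{-2\kappa d}$; numerically the approach
is monotone from above ($\sim$24% high at $\kappa d = 3$, 10% at 5,
2.5% at 8), while the intermediate Bessel-ratio form
$l_p \ell_B \tau^2 K_1(\kappa d)/I_1(\kappa d)$ is already accurate to a
few percent at $\kappa d = 3$.

**Assembling the barrier.** Only the self-energy of the *in-pore* portion is
modelled, so the barrier along the reaction coordinate is taken as
$V_p(z_p) = \Delta\Omega_p(l_p(z_p))$ — the minimal choice consistent with
the occupancy geometry, peaking on the plateau. (When the wall is also
charged the mean-field term is added.) For transport runs the self-energy is
precomputed on 101 occupancy values and spline-interpolated (monotone
Hyman splines), making the effective potential cheap to evaluate on dense
transport grids.

With the α-Hemolysin parameter set ($d = 8.5$ Å, $a = 5$ Å,
$\tau = 0.29$ e/Å, $L_m = 5$ nm, $L_p = 10$ nm, neutral wall, 120 mV) the
barrier per unit polymer length is $\max_z V_p/L_p = 9.09\ k_BT$/nm at
0.04 M and 3.33 $k_BT$/nm at 0.1 M — reproducing the salt-induced switch
from barrier-dominated trapping (the local velocity changes sign inside the
capture region) to drift-dominated translocation (velocity positive
throughout):

```{r alphahl}
sys04 <- pore_system(a = 0.5, d = 0.85, Lm = 5, Lp = 10,
                     sigma_p = 2.9 / pi, sigma_m = 0, dV = 0.12,
                     electrolyte = electrolyte(0.04))
zp <- seq(0, sys04$zex, length.out = 61)
max(image_barrier_potential(sys04, zp)) / sys04$Lp   # ~9 kBT/nm
```

### 1.5 Trapping criticals

The mean velocity changes sign at critical values of the pressure, the salt
density and the polymer length; all three are found as bracketed roots of
the full $\bar v_p(\cdot)$ (grid scan + `uniroot`). Closed forms from the
high-salt and dilute-salt expansions of the annular solution are exposed
alongside: the high-salt trapping density
$\rho^*_> = \frac{2}{\pi \ell_B}\left[\frac{(\sigma_p - \sigma_m)\,\beta e
\Delta V}{\gamma a^2 \beta\Delta P}\right]^2$ (derived by setting the
planar-screening drift velocity to zero; it agrees with the numerical root
to $\sim$15% once $\kappa a \gtrsim 10$), and the dilute-salt forms built
from the expansion coefficients
$a_p = -\tfrac{a}{2} + \tfrac{a d^2 \ln(d/a)}{d^2 - a^2}$,
$a_m = \tfrac{d}{2} - \tfrac{a^2 d \ln(d/a)}{d^2 - a^2}$, which we
re-derived independently by Taylor-expanding the annular Bessel solution at
small $\kappa$.

## 2. The IFTP engine (long, fluctuating polymers)

### 2.1 Model

In reduced units (segment length, $k_BT$, solvent friction per monomer all
unity) the translocation coordinate $\tilde s$ obeys overdamped Brownian
dynamics,
$$\tilde\Gamma(\tilde t)\,\frac{d\tilde s}{d\tilde t}
  = (1 - \gamma')\left[\frac{1}{N_0 - \tilde s} - \frac{1}{\tilde s}\right]
    + \tilde f + \tilde\zeta(\tilde t),$$
where the effective friction $\tilde\Gamma = \tilde R + \tilde\eta_p$
(pore-driven) or $\tilde R + \tilde\eta_p + \tilde s$ (end-pulled, whose
straightened trans-side subchain adds friction $\tilde s$). The tension
front $\tilde R$ separates the mobile part of the cis subchain from the
still-equilibrated part; iso-flux means the monomer flux
$\tilde\phi = d\tilde s/d\tilde t$ is uniform across the mobile domain, so
$\tilde\phi = \tilde f_{tot}/\tilde\Gamma$. In the strong-stretching regime
(very strong force, mobile subchain fully straightened — the only force
regime in scope) the front obeys, during tension propagation (TP),
$$\dot{\tilde R} = \frac{B(\tilde R)\,\tilde\phi}{1 - B(\tilde R)},
 \qquad B(\tilde R) = \nu A_\nu^{1/\nu} \tilde R^{(\nu-1)/\nu},$$
from $\tilde R = A_\nu N^\nu$ with $N = \tilde l + \tilde s$ the tensed
segments and $\tilde l = \tilde R$. When $N$ reaches $N_0$ the process
enters post-propagation (PP) and the front shrinks with the flux,
$\dot{\tilde R} = -\tilde\phi$, until $\tilde s = N_0$.

Design decisions here:

* **Initialization.** The tension is seeded with one segment:
  $N(0) = 1$, $\tilde R(0) = A_\nu$, $\tilde s(0) = 0$. This puts
  $B = \nu A_\nu = 0.68 < 1$ for the standard 3D parameters
  ($\nu = 0.588$, $A_\nu = 1.15$); the solver verifies $B < 1$ and refuses
  parameter sets that violate it (e.g. $\nu A_\nu \ge 1$), because the TP
  equation is singular there.
* **PP front sign.** Mass conservation with $\tilde l = \tilde R$ and a
  growing $\tilde s$ forces the front to *shrink* in PP; we integrate
  $\dot{\tilde R} = -\tilde\phi$ from $\tilde R(N_0)$ to 0.
* **Entropic term.** The $(1-\gamma')$ term is singular at the chain ends;
  when enabled it is evaluated with $\tilde s$ clamped to $[1, N_0 - 1]$.
  It is off by default (negligible in the strong-stretching regime) and off
  in all scaling runs.
* **Stiff (rodlike) chains.** $\tilde R(N) = N$ makes tension propagation
  instantaneous; the solver skips TP and integrates PP from
  $\tilde R = N_0$ with the trans-side friction $\tilde s$ included, giving
  the exact closed form
  $\tilde\tau = (\tilde\eta_p N_0 + N_0^2)/\tilde f$ (reproduced to the
  integrator tolerance, e.g. 103 for $N_0 = 100$, $f = 100$,
  $\eta_p = 3$).

### 2.2 Integration

Deterministic runs use `deSolve::lsodar` (adaptive BDF/Adams with root
finding) at `rtol = atol = 1e-10`: one sparse pass detects the TP$\to$PP
switch ($\tilde R + \tilde s = N_0$) and termination ($\tilde s = N_0$)
as events, a second pass produces dense trajectory output over the known
stage windows when a trajectory is requested. Stochastic runs use
fixed-step Euler–Maruyama ($\Delta\tilde t = 10^{-3}$ default, noise
variance $2\tilde\Gamma k_BT \Delta\tilde t$, $k_BT = 1$), with the same TP
front equation, the front clamped at its seeded value $A_\nu$ (this keeps
$B < 1$ for any noise realization since $B$ decreases with $\tilde R$),
reflection of $\tilde s$ at the pore entrance, and a mandatory recorded
seed. As the noise temperature is taken to zero the stochastic path
converges to the deterministic one (verified pathwise in the tests at
fixed step). The distributions from which a stochastically sampled force or
front amplitude would be drawn are not specified by the theory as packaged
here; thermal noise via $\tilde\zeta$ is the only stochastic element.

### 2.3 Waiting times and scaling

The waiting-time profile $w(k)$ — the time spent with
$\tilde s \in [k-1, k)$ — is obtained by inverting the monotone
deterministic trajectory (interpolated crossing times), or accumulated per
bin during stochastic integration. It rises through TP (growing mobile
friction), peaks at the TP$\to$PP transition, and falls in PP for
pore-driven chains; for end-pulled chains the PP profile is nearly flat
(the straightened cis+trans friction is conserved as segments trade sides).

The translocation-time scaling $\tilde\tau \propto N_0^\alpha$ is fitted as
a log-log least-squares slope. Two rescalings isolate the asymptotic
contributions: subtracting the pore-friction term $\tilde\eta_p N_0/\tilde f$
collapses the pore-driven curves for different $\eta_p$ onto
$A_\nu N_0^{1+\nu}/[(1+\nu)\tilde f]$ with exponent
$1 + \nu = 1.588$; subtracting the full cis-side bracket from the
end-pulled time leaves the trans-side term $N_0^2/(2\tilde f)$ with
exponent 2. On synthetic pure power laws the fit is exact to $10^{-10}$.

## 3. What the checks do and do not show

The package's validation is desk-scale and self-contained: closed forms
(flat-potential rate and time, the drift capture identity, the stiff-chain
time), independent numerical oracles (a finite-difference boundary-value
solver for the annular field, $10^6$-point Riemann sums, 30-digit
arbitrary-precision evaluations of the dielectric jump function frozen into
the tests), and the printed parameter sets of the study the models come
from. Problem sizes were chosen for that purpose: scaling sweeps use
$N_0 \le 8192$ (7 chain lengths × 3 frictions, a few seconds), transport
grids 2 001 points, self-energy tabulation 101 occupancy values.

The engines share the limitations of their models: the electrohydrodynamic
engine is mean-field (no ion–ion correlations, so no charge inversion or
mobility reversal by multivalent cations), linear-response (Debye–Hückel)
in the electrostatics, rigid-rod in the polymer, and single-cylinder in the
image-charge geometry; the IFTP engine covers only the strong-stretching
force regime for fully flexible or rodlike chains, with no explicit capture
or escape stage (the pore is assumed already filled, appropriate for
$L_m \ll L_p$). Agreement of the test suite therefore demonstrates faithful
implementation of these models, not their validity beyond the regimes for
which they were built.
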