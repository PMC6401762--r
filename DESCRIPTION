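Package: nanotransloc
Title: Electrohydrodynamics and Tension-Propagation Dynamics of Polymer
    Translocation Through Nanopores
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling driven polymer translocation through
    nanopores in the two complementary regimes where theory is tractable.
    For short, stiff polymers a steady-state electrohydrodynamic engine
    couples linearized Poisson-Boltzmann electrostatics in the annular
    pore geometry, Stokes flow (electrophoresis, electroosmosis and
    pressure-driven streaming flow), mean-field polymer-membrane
    interactions and dielectric image-charge self-energies to a
    Smoluchowski description of the translocation coordinate, yielding
    capture rates, translocation times, density profiles and the critical
    pressures, salt densities and polymer lengths at which the molecule
    is trapped. For long, fluctuating polymers the iso-flux
    tension-propagation (IFTP) equations are integrated for pore-driven
    and end-pulled translocation in the strong-stretching regime, giving
    waiting-time profiles and translocation-time scaling exponents.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
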