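Package: fepddg
Title: Post-Simulation Analysis of Alchemical Free Energy Calculations
    for Mutation-Induced Binding Changes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimates free energy differences across alchemical lambda
    states from cross-evaluated reduced potential energies using the
    multistate Bennett acceptance ratio (MBAR), the two-state Bennett
    acceptance ratio (BAR) and exponential averaging, with asymptotic
    uncertainties.  Provides lambda-schedule quality diagnostics (overlap
    matrix against the 0.03 neighbor-overlap criterion), equilibration
    discard and convergence-versus-time analysis, replicate aggregation
    and thermodynamic-cycle assembly of relative binding free energies
    (DDG) for both alchemical-mutation and double-annihilation cycles, a
    center-of-mass-distance bound-state diagnostic (P_bound), and linear
    regression scoring of calculated against experimental drug-sensitivity
    changes.  Includes readers for GROMACS dhdl .xvg output and plain
    tabular formats, a synthetic-data generator with analytic harmonic
    free energies for validation, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
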