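# fepddg

Post-simulation analysis of alchemical free energy perturbation (FEP)
calculations aimed at one question: **how much does a protein mutation change
the binding free energy of a drug?** The package is written for computational
chemists and structural bioinformaticians who already have alchemical MD
output (cross-evaluated potential energies along a λ schedule, center-of-mass
distance traces, experimental sensitivity data) and need the statistics on
top of it: free energy estimation, schedule diagnostics, replicate and cycle
assembly, bound-state checks, and scoring against experiment.

## What it computes

**Free energies.** Samples from K λ states with reduced potentials
u<sub>n</sub>(k) = U<sub>k</sub>(x<sub>n</sub>)/k<sub>B</sub>T are combined
with the multistate Bennett acceptance ratio (MBAR), solved self-consistently:

    f_k = −ln Σ_n exp(−u_n(k)) / Σ_l N_l exp(f_l − u_n(l)),   f_1 = 0

with uncertainties from the MBAR asymptotic covariance. The two-state Bennett
acceptance ratio (BAR) and exponential averaging (EXP) are included as
special cases and cross-checks.

**ΔΔG assembly.** Two thermodynamic cycles are supported:

* *alchemical mutation* ("MutationFEP"): ΔΔG = ΔG²_mutation(bound) −
  ΔG¹_mutation(free), with σ²⁻¹ = √((σ¹)² + (σ²)²) over independent
  replicates;
* *double annihilation* ("MP-CAFEE"): ΔΔG = ΔG²_bind(mutant) −
  ΔG¹_bind(wild-type), with σ taken from the mutant leg's replicate spread
  (the convention of that protocol; full propagation is a switch).

Replicates whose MBAR solve did not converge are excluded with the reason
recorded, not silently dropped.

**Diagnostics.** The MBAR overlap matrix with the minimum neighbor overlap
against the 0.03 adequacy criterion; equilibration discard; ΔG as a function
of accumulated simulation time; and P_bound, the percentage of λ trajectories
whose mean protein–drug COM distance stays strictly below
T = ave + 6 × s.t.d. of the unperturbed (λ = 0) runs.

**Evaluation.** Experimental K_i / IC50 ratios are converted by
ΔΔG_exp = RT ln(mut/wt) and compared with calculated ΔΔG by ordinary least
squares, reporting R².

**Synthetic ground truth.** One-dimensional harmonic λ paths have closed-form
free energies (f_k = ½ ln(K_k/K_1)), so every estimator and every pipeline
stage can be validated against an exact answer; generators for planted-truth
cycles and bound/escaping COM trajectories complete the test bed.

## Worked example

```r
library(fepddg)

# three harmonic states with analytic end-to-end Delta f = 0.5*ln 4 = ln 2
d   <- make_harmonic_dataset(spring_constants = c(1, 2, 4),
                             n_per_state = 1000, seed = 42)
est <- mbar_solve(d$rps)
est
#> MBAR estimate over 3 states (converged after 3 iterations)
#>   end-to-end Delta f = 0.6935 +/- 0.0162 kT  (0.4134 +/- 0.0097 kcal/mol)

overlap_matrix(d$rps, est)
#> Overlap matrix (3 states): min neighbor overlap = 0.3245 (passes criterion 0.03)

# planted-truth cycle: leg free energies -2.0 and -0.5 kcal/mol, truth +1.5
sc <- make_cycle_scenario(-2.0, -0.5, n_replicates = 3, seed = 5)
leg_free  <- aggregate_leg(lapply(sc$leg1, mbar_solve), "mutation_free")
leg_bound <- aggregate_leg(lapply(sc$leg2, mbar_solve), "mutation_bound")
ddg_mutation(leg_free, leg_bound, system = "toy", mutation = "A1B")
#> MutationFEP DDG (toy A1B) = 1.5204 +/- 0.0320 kcal/mol
```

The estimate sits within one reported standard error of ln 2, the overlap
diagnostic confirms the schedule is dense enough, and the assembled ΔΔG
recovers the planted +1.5 kcal/mol within its quadrature uncertainty.

A command-line interface with subcommands
`estimate | diagnose | ddg | pbound | evaluate | synth` is installed at
`exec/fepddg` inside the package; run it without arguments for usage.

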