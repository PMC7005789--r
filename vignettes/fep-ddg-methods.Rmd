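---
title: "Methods: free energy estimation and ΔΔG assembly in fepddg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: free energy estimation and ΔΔG assembly in fepddg}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fepddg)
```

## The estimation problem

An alchemical FEP calculation interpolates a system between two end states
with a coupling parameter λ ∈ [0, 1] — here either a wild-type→mutant residue
transformation (performed once in the drug-free protein and once in the
drug-bound complex) or a stepwise annihilation of the drug's Coulomb and van
der Waals interactions with its environment. Each of the K λ windows is
simulated separately, and every stored configuration's potential energy is
re-evaluated at all K windows. After division by k<sub>B</sub>T this yields
the reduced potential matrix u (n samples × K states) that
`reduced_potential_set()` holds and all estimators consume.

`mbar_solve()` finds the dimensionless free energies f<sub>k</sub> from the
MBAR self-consistent equations

$$f_k = -\ln \sum_{n} \frac{e^{-u_n(k)}}{\sum_l N_l\, e^{f_l - u_n(l)}},
\qquad f_1 \equiv 0,$$

which are the statistically optimal combination of all samples from all
states. The estimator assumes (i) samples are drawn from the equilibrium
Boltzmann distribution of their origin state, and (ii) samples are
uncorrelated — in practice approximately satisfied after the equilibration
discard, and improvable with `statistical_inefficiency()` +
`subsample()`. Uncertainties come from the MBAR asymptotic covariance,
computed through the SVD of the weight matrix so only K×K systems are ever
factorized. BAR (`bar_estimate()`) is the exact two-state special case and
exponential averaging (`exp_estimator()`) the one-sided limit; both serve as
independent cross-checks in the test suite rather than as the production
path.

Energies are dimensionless internally; conversions use
k<sub>B</sub> = 0.0019872041 kcal/(mol·K) (and 0.0083144621 kJ/(mol·K) for
engine files), at a configurable temperature defaulting to 300 K, the
simulation temperature this analysis layer is normally paired with.

## Numerical choices

* **Solver.** Self-consistent iteration seeded by chained forward
  exponential averages, switching to a damped Newton step (with the analytic
  Hessian of the MBAR objective) once the residual drops below 10⁻². The
  convergence tolerance is max |Δf<sub>k</sub>| < 10⁻⁸ kT with
  `max_iter = 10000`. After convergence the solution is polished with a few
  more Newton steps toward machine precision: this costs microseconds and
  makes identities that hold only at the exact fixed point (notably
  overlap-matrix row sums equal to 1) hold to ~10⁻¹⁴ instead of ~10⁻⁸.
* **Non-convergence** is a *flag* (`converged = FALSE`), never an exception:
  a replicate that fails to converge is real data that downstream
  aggregation must see and exclude explicitly. `overlap_matrix()` refuses
  non-converged input, since its weights are meaningless away from the fixed
  point.
* **Zero-sample states are retained.** States with N<sub>k</sub> = 0 only
  appear as evaluation columns; MBAR estimates their free energies by
  reweighting the pooled samples, so dropping them would discard a
  well-posed estimate. The under-determined error fires only when fewer than
  two states carry samples. (Duplicate λ descriptors are likewise harmless
  to the solver and are left untouched.)
* **Per-sample reference shifts.** Engine dhdl files report energies
  relative to the sampling state (the self column is zero). MBAR weights are
  invariant under adding a per-sample constant to a row of u, so this
  convention is accepted as-is; the package's own u_kln format may carry
  either convention.

## Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `temperature` | 300 | K | simulation/assay convention |
| `tolerance` (MBAR) | 1e-8 | kT | far below any statistical error |
| `max_iter` | 10000 | – | poor-overlap schedules converge slowly |
| `t_discard_ns` | 0 (API); 2 / 1 (CLI mutation / annihilation presets) | ns | typical equilibration windows of the two protocols |
| overlap `criterion` | 0.03 | – | published adequacy threshold for neighbor overlap |
| P_bound multiplier | 6 | σ | makes a false unbound call on a bound run negligible |
| `full_error_propagation` | FALSE | – | annihilation σ convention uses the mutant leg only |

## Design decisions on genuinely open points

* **"Neighbor overlap" is the minimum**, over adjacent pairs, of the two
  off-diagonal overlap-matrix entries — the stricter reading of the scalar
  criterion (a mean can hide one broken seam in the schedule). The matrix
  itself is O<sub>ij</sub> = N<sub>j</sub> Σ<sub>n</sub> W<sub>ni</sub>
  W<sub>nj</sub>, the convention of the standard alchemical-analysis
  toolchain, whose rows sum to 1 exactly at the MBAR fixed point.
* **Bound-state classification** uses a *strict* inequality (mean COM
  distance < T), pools reference samples across the unperturbed replicates
  (a per-replicate-means alternative is a flag), and applies the same
  equilibration discard as the free energy analysis *before* averaging —
  a trajectory that starts bound and escapes should be judged by its
  production portion.
* **Experimental conversion.** ΔΔG_exp = RT ln(ratio) at the assay
  temperature, the standard thermodynamic reading of K_i ratios; IC50 ratios
  are treated identically, which assumes the Cheng–Prusoff factor is shared
  across mutants of one system (flagged as an approximation). A log10 unit
  mode is available. Regression is calculated-on-experimental OLS; R² is the
  squared Pearson correlation, so the axis choice affects slope and
  intercept only.
* **Annihilation sub-legs.** A per-replicate complex-minus-solvent
  subtraction is the default in `combine_sublegs()`; a shared mean solvent
  leg is the alternative, since published protocols differ on this point.
* **σ conventions.** Replicate spread is the sample (n−1) standard
  deviation — the unbiased small-n convention for 3–6 replicates. With a
  single surviving replicate σ is reported as 0 with a warning rather than
  NA, so downstream quadrature stays defined; treat such legs with caution.

## What the synthetic generators emulate — and what they do not

`make_harmonic_dataset()` draws from one-dimensional harmonic states
(Gaussians with variance 1/K<sub>spr</sub>), because their free energies are
closed-form (f<sub>k</sub> = ½ ln(K<sub>spr,k</sub>/K<sub>spr,1</sub>)) and
their mutual overlap is tunable through spring constants and centers — the
0.03-overlap regime can be targeted directly. `make_cycle_scenario()` plants
leg free energies by geometric spring interpolation, with replicates
differing by derived sub-seeds; `make_com_trajectories()` produces
stationary ("bound") or progressively drifting ("escape") COM distance
series, the qualitative contrast between a mutation-only perturbation and a
late-stage annihilation window. Test problem sizes are deliberately small
(hundreds to a few thousand samples per state, 8–27 states), chosen so the
analytic error bars are tight enough to detect estimator bias while the full
suite stays fast.

These generators validate the *statistics*: estimator consistency, error
calibration, cycle algebra, classification arithmetic. They do not emulate
force-field energetics, conformational kinetics, correlated sampling, or
real protein–ligand geometry — so passing tests demonstrate correctness of
the analysis layer, not the accuracy of any particular MD protocol that
feeds it.

## Known limitations

* No thermodynamic-integration or weighted-histogram estimators; input must
  be cross-evaluated (dH/dλ-only files are rejected with an explanatory
  error).
* COM distances are consumed precomputed; the package does not read
  coordinate trajectories.
* The λ schedules themselves are taken as given (or evenly spaced when only
  a count is supplied); no automated schedule optimization.
* Cycle assembly covers single two-leg cycles, not multi-mutation
  cycle-closure networks or cross-method consensus.
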