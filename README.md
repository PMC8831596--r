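# flexfold

Integrative, restraint-based structure determination of flexible,
five-fold-symmetric membrane-protein domains from solution NMR and ESR
observables — the kind of problem posed by the intracellular domain (ICD) of
pentameric ligand-gated ion channels, which is too flexible for
crystallography or cryo-EM but visible to paramagnetic relaxation
enhancement (PRE), DEER, NOEs, chemical shifts and amide temperature
coefficients.

The package is aimed at structural-NMR/ESR practitioners and method
developers who want the full pipeline as tested, reusable code:

* **Restraint derivation.** Intensity ratios *I/I₀* and diamagnetic
  linewidths are inverted through
  *I/I₀ = R₂ᵈⁱᵃ e^(−R₂ˢᵖ t) / (R₂ᵈⁱᵃ + R₂ˢᵖ)* and the Solomon–Bloembergen
  relation *R₂ˢᵖ = (K/r⁶)(4τc + 3τc/(1+ωH²τc²))* into label–amide distances,
  with window rules for unbroadened and vanished peaks; DEER distributions
  are decomposed into the two pentagon modes of a C5 ring
  (d_diag/d_adj = 2 cos 36° = 1.618…) and become harmonic inter-subunit
  restraints; NOE classes become flat-bottom bounds; temperature
  coefficients (<4.5 ppb/K in magnitude) flag hydrogen bonds; R₁/R₂
  exponential fits, hetNOE ratios and IPAP-derived RDCs characterize
  dynamics and alignment.
* **Folding.** A coarse-grained, exactly C5-symmetric simulated-annealing
  sampler folds the asymmetric unit under the combined score
  S_total = S_physics + S_knowledge + S_DEER + S_PRE + S_NOE, inside an
  iterative generate → rank → cluster (greedy leader, 3 Å cutoff) → reseed
  protocol with elitism and a plateau convergence rule.
* **Validation.** Restraint Q-factors
  Q = √(Σ(r_exp−r_calc)² / Σ r_exp²) per class and on a held-out ~10% PRE
  set, hydrogen-bond secondary-structure assignment and disorder fractions,
  HOLE-style pore-radius profiles, lateral-portal bottlenecks and
  salt-bridge distances.
* **Synthetic data.** A generator forward-models every observable from a
  known toy pentamer (two helices plus an anchored flexible loop per
  subunit) with seeded noise, so the whole pipeline runs and is tested at
  desk scale with a known answer.

## Worked example

Simulate a study, derive restraints, hold out 10% of the PREs, fold, and
validate:

```r
library(flexfold)

bundle     <- make_bundle(file.path(tempdir(), "demo"), master_seed = 1)
restraints <- derive_restraints(bundle)
table(restraints$kind)
#> DEER  NOE  PRE
#>    8   89  531

split   <- holdout_split(restraints[restraints$kind == "PRE", ], 0.1, seed = 1)
working <- bind_restraints(split$working,
                           restraints[restraints$kind != "PRE", ])

fit <- run_protocol(protocol_config(master_seed = 1), working,
                    ss = bundle$gt$ss, templates0 = list(toy_template()))
fit$records
#>   iteration best_total n_clusters top_population rep_move
#> 1         1   33.55284         10              1       NA
#> 2         2   23.22036          4              6 6.473876
#> 3         3   22.66258          1             10 2.163856
#> 4         4   22.26153          1             10 1.762250
#> 5         5   22.15894          1             10 1.144197
fit$converged
#> [1] TRUE

ca_rmsd(fit$ensemble$models[[1]], bundle$gt$structure)
#> [1] 2.31

q_report(fit$ensemble, working, free = split$free)
#> Q-factor report
#>   q_noe      0.0000  (n = 89)
#>   q_pre      0.0233  (n = 478)
#>   q_deer     0.0126  (n = 8)
#>   q_pre_free 0.0224  (n = 53)
```

Reading the output: the iteration log shows the non-increasing best total
score, the cluster count collapsing to a single basin (population 10 of 10)
and the representative motion falling below half the cluster cutoff, which
together trigger convergence.  The best model lands 2.31 Å CA RMSD from the
generating ground truth, and the free-set PRE Q-factor (restraints never
seen during folding) is 0.022 — the distances the model predicts for
held-out data agree with experiment to about 2%.

The same stages are scriptable from a shell via `inst/exec/flexfold`
(`simulate`, `derive`, `protocol`, `qreport`, `pore`, `measure`); each run
writes a JSON manifest with the seeds used, so any result is reproducible
from its manifest alone.

Measurement utilities (`pore_profile`, `lateral_portal_radius`,
`salt_bridge_distances`, `assign_secondary_structure`, `measure_distance`)
work on any multi-model PDB read with `read_structure`, including a locally
downloaded deposited ensemble of the real receptor.

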