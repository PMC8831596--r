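---
title: "Restraint-based ensemble modeling of a flexible C5 channel domain"
author: "flexfold"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Restraint-based ensemble modeling of a flexible C5 channel domain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flexfold)
```

## The problem

Pentameric ligand-gated ion channels carry a large intracellular domain (ICD)
between two of their transmembrane helices.  Much of this domain is
intrinsically flexible -- a long loop flanked by two amphipathic helices --
and therefore invisible to crystallography and cryo-EM.  Solution NMR and ESR
can still see it: paramagnetic relaxation enhancement (PRE) reports distances
between an engineered nitroxide label and every amide in the subunit,
double electron-electron resonance (DEER) reports inter-subunit label
distances, NOEs and amide-proton temperature coefficients report contacts and
hydrogen bonds, and chemical shifts report secondary structure.  None of
these observables is a structure; `flexfold` implements the pipeline that
turns them into one: observable-to-restraint conversion, restraint-scored
C5-symmetric conformational sampling inside an iterative
fold/rank/cluster/reseed protocol, and validation with held-out restraints
and pore-geometry analytics.

Because the original spectra cannot ship with a package, a synthetic-data
module forward-models every observable from a known toy pentamer, so the
entire pipeline is exercised end to end at desk scale with a known answer.

## Observable-to-restraint conversions

**PRE.** The measured quantity is the paramagnetic/diamagnetic peak intensity
ratio $I/I_0$ and the diamagnetic linewidth $\Delta\nu$.  With
$R_2^{dia}=\pi\Delta\nu$, the two-condition intensity model

$$\frac{I}{I_0} = \frac{R_2^{dia}\,e^{-R_2^{sp}t}}{R_2^{dia}+R_2^{sp}}$$

is inverted for the rate enhancement $R_2^{sp}$ by bracketed root finding
(`r2sp_from_ratio`; the map is strictly decreasing, so the root is unique),
and the Solomon-Bloembergen relation

$$R_2^{sp} = \frac{K}{r^6}\left(4\tau_c + \frac{3\tau_c}{1+\omega_H^2\tau_c^2}\right)$$

is inverted in closed form for the electron-proton distance $r$
(`pre_distance`).  Defaults: $K = 1.23\times10^{-32}\,\mathrm{cm^6 s^{-2}}$
(the standard nitroxide value), $\tau_c = 10$ ns, evolution period
$t = 10$ ms, spectrometer field 700 MHz.  All are `pre_params()` keys.

Ratios are only quantifiable in a window (defaults 0.10--0.85).  Above the
ceiling the peak is unbroadened and only a lower bound is known; at or below
the floor the peak has vanished and only an upper bound is known.  The bound
distances default to the window edges themselves -- obtained by inverting the
ceiling and floor ratios at the residue's own linewidth -- so a ratio that
noise pushes across the threshold produces a bound the true distance almost
satisfies.  A fixed pair of bound distances (e.g. 12 and 23 A) can be set
instead, but is only consistent with one particular linewidth.  Quantifiable
ratios give two-sided restraints centered on the converted distance with a
$\pm 4$ A band; the band reflects conventional PRE practice (label-linker
flexibility in real experiments), and it is what limits the attainable
coordinate precision to a few Angstrom.

**DEER.** A C5 ring with one label per subunit has exactly two unique
inter-label distances, adjacent and diagonal, with the pentagon ratio
$d_{diag}/d_{adj} = 2\cos 36^\circ = 1.618\ldots$  `split_pentamer_modes`
fits a two-Gaussian mixture to the input distance distribution (least squares
on the density grid, Nelder-Mead, golden-ratio initialization); if only one
mode is resolvable it is taken as adjacent and the diagonal inferred by the
ratio, flagged.  Each mode becomes a harmonic restraint on the corresponding
chain offset with weight $1/\sigma^2$.  Raw DEER time-trace inversion is out
of scope; distributions are the input contract.

**NOEs** map to flat-bottom restraints with class bounds
strong/medium/weak $\to$ 3.5/4.5/6.0 A upper, 1.8 A lower (configurable).
**Temperature coefficients** are the OLS slope of the amide $^1$H shift (ppb)
against temperature; $|$slope$| < 4.5$ ppb/K flags a hydrogen bond.  The
magnitude criterion is used because amide coefficients are conventionally
negative and a signed threshold would flag every strongly negative (i.e.
non-bonded) amide.  **Relaxation** series are fit to
$I(\tau)=A e^{-R\tau}$ by Levenberg-Marquardt with a deterministic
log-linear initializer; the **hetNOE** is the saturated/unsaturated intensity
ratio with propagated uncertainty.  **RDCs** come from the IPAP
$^{15}$N shift difference (ppm converted at the $^{15}$N frequency), aligned
minus isotropic arm.  Relaxation rates, hetNOE, temperature flags and RDCs
are used for annotation and validation, not as folding restraints.

## Scoring

Models are ranked by
$S_{total} = w_p S_{physics} + w_k S_{knowledge} + w_d S_{DEER} + w_P S_{PRE} + w_n S_{NOE}$,
lower is better, all weights 1 by default; units are arbitrary score units
and only the ranking matters.

The coarse-grained stand-in energy (`cg_energy`) replaces the all-atom force
field of the original protocol with four CA-level terms: a virtual-bond
spring (target 3.8 A, k = 10), a flat-bottom pseudo-angle band
(75--150 degrees, k = 20), a soft-sphere repulsion between nonbonded CA
(onset 4.0 A, k = 10) and, as the knowledge term, a pseudo-dihedral bias on
annotated helical quadruples whose target is the exact pseudo-dihedral of the
package's ideal CA helix (about 50.4 degrees), so generator helices sit at
the bias minimum by construction.  Restraints use the harmonic (DEER),
sigmoid (PRE, steepness 1 per Angstrom; two-sided bands get one sigmoid per
edge, so a restraint satisfied at its center retains a small positive floor)
and flat-bottom (NOE) potentials.

The Q-factor,
$Q=\sqrt{\sum_i (r_{exp,i}-r_{calc,i})^2 / \sum_i r_{exp,i}^2}$, is computed
per restraint class with $r_{calc}$ the ensemble-mean distance.  Bound-only
restraints enter through their violated bound: $r_{exp}$ is the bound and the
discrepancy is the violation magnitude, so satisfied bounds contribute zero
to the numerator but still normalize the denominator.  `holdout_split`
reserves a seeded 10% of the PRE restraints before folding and
`q_report` evaluates the free set separately (the free-Q analog of a
crystallographic R-free).

## Sampling

`mc_fold` anneals the asymmetric unit -- one subunit at CA resolution --
under Metropolis dynamics, replicating it about the fixed C5 frame (z axis)
and scoring the whole pentamer at every step, so every emitted model is
exactly symmetric and only one fifth of the system is sampled.  The move set
is bond-preserving by construction: pivot rotations at loop/coil residues,
crankshaft rotations of short loop windows, and rigid-body translations and
rotations of the whole subunit; helical segments only ever move rigidly.
Two standard annealing devices matter in practice:

* *soft-core repulsion ramp* -- the repulsion constant is scaled up the
  ladder (default 0.3 to 1.0, full strength over the final rungs), letting
  restraints establish the topology before sterics harden; the best model is
  tracked only over full-repulsion rungs;
* *temperature-scaled move sizes* -- move sigmas shrink as
  $\sqrt{T/T_1}$ (floored at 0.2), so cold rungs relax residual strain
  instead of rejecting every proposal.

The default ladder is 2.5 to 0.08 score units over 6 rungs, 700 moves per
rung (about 4200 energy evaluations per fold, well under a second for a
60-residue subunit).  The whole trajectory is reproducible bit-for-bit from
the schedule seed: the inner loop runs in compiled code but draws from R's
RNG.

Distance data alone cannot fix the hand of the assembly: every restraint and
every coarse-grained term is invariant under mirror inversion of the subunit
(rigid helices never invert internally, and an inverted arrangement
reproduces all distances to within the restraint bands).  The original study
broke this degeneracy with homolog templates in the first round; the package
does the same with `toy_template()`, a deterministic subunit that encodes
only the generic architecture (two near-vertical helices on the ring, a
strain-screened self-avoiding loop) and none of a particular ground truth's
loop conformation.

## The iterative protocol

`run_protocol` loops generate-pool / rank / cluster / reseed.  Round 1 folds
`n_pool` models from the round-1 templates with the flexible segments
*rebuilt* as fresh self-avoiding walks between the template's helix
endpoints (the fragment-insertion analog: pool diversity concentrates where
the data must decide); later rounds perturb the previous round's cluster
representatives and anneal with a colder ladder (temperatures scaled by 0.2,
perturbation 0.5) so they refine within the reseeded basins.  The top
`top_m` models are clustered by greedy leader clustering on score order --
chosen over unspecified alternatives because it is deterministic and
guarantees every member lies within the cutoff (3 A CA RMSD) of its
representative.  With elitism (default on, and switchable off) the incumbent
best fold joins every pool, making the best score non-increasing across
iterations.

Convergence is a pure function of the iteration log: declared when the best
score improves by less than `max(tol, tol_rel * |best|)` (defaults 1.0 and
0.02) over the last `window = 2` iterations *and* the top representative
moved less than half the cluster cutoff since the previous iteration.  With
an infinite tolerance the plateau test is vacuous and convergence is
declared at the first evaluation (after `window` iterations); the motion
test is bypassed in that case, since a vacuous plateau makes basin identity
meaningless.  The original study reported rounds-to-convergence without
stating a criterion; this two-part rule is the package's own, configurable
choice.  Final representatives pass through `minimize_fold`, a seeded
small-move descent that provably never raises the score.

Desk-scale defaults are a pool of 40 with top 10 kept, at most 6 iterations;
the published-scale values (1000/100, more rounds) are ordinary arguments
and differ only in wall time.

## The synthetic system, and what passing it does (not) show

`build_toy_pentamer` emulates the study architecture at 60 residues per
subunit: a 20-residue descending helix on the ring (transmembrane anchor
analog), a 20-residue flexible loop whose middle residue is anchored within
8 A of the second helix (the "B"-shaped double-loop analog), and a
20-residue ascending membrane-associated-like helix.  The loop is a guided
self-avoiding walk, rejection-sampled until the C5 assembly is essentially
strain-free, so the ground truth is a fair point of the model's own energy
landscape.  Order parameters are 0.85 in helices and 0.30 in the loop
(internal correlation times 500 and 50 ps), which reproduces the diagnostic
phenomenology: positive hetNOE in helices, negative in the loop.

Label placement mirrors the study design: nine single-cysteine PRE sites
(about one per seven residues -- comparable restraint density to the
hundreds of PREs per subunit in the original study, and compensating for the
absent fragment library), four of them also DEER-probed.  The multi-site
DEER data matter: a single DEER site fixes only one ring radius and leaves
the subunit's orientation in the ring undetermined; four sites pin it.
Noise defaults are a 2% intensity coefficient of variation and 2 ppb shift
jitter, typical of well-behaved solution spectra.

Forward models: PRE through the same Solomon-Bloembergen and two-condition
intensity equations the conversion inverts; DEER as an equal-weight
two-Gaussian mixture at the true adjacent/diagonal distances (5 + 5 pairs in
a pentagon); relaxation through the Lipari-Szabo spectral density (a
generator choice -- the study measured rather than modeled its relaxation);
RDCs through the alignment-tensor equation with NH vectors taken as the
local backbone direction; temperature coefficients drawn from
disjoint slope ranges for bonded and non-bonded amides; NOE contacts from
all CA pairs under 5.5 A (at CA resolution this includes the
helix-diagnostic $i,i+3$ contacts; the all-atom $i,i+4$ amide contact
corresponds to a CA separation just above the cutoff).

At zero noise every forward/inverse pair closes to numerical precision
(asserted in the test suite).  What passing the recovery test shows is that
the *pipeline* -- conversion, scoring, sampling, clustering, validation --
is internally consistent and that restraints of this density and quality
determine the toy fold to a few Angstrom.  What it does not show: that the
coarse-grained stand-in energy rivals an all-atom force field, that real
(sparser, assignment-limited, linker-broadened) data behave like the
forward models, or that the template prior is available for an unknown
system without homologs.

Typical behaviour of the desk-scale protocol (pool 40, top 10, up to 6
iterations, five master seeds, about 90 seconds total on one CPU): median
recovery of 2--5 A CA RMSD over the 300-CA pentamer with free-set PRE
Q-factors an order of magnitude below 0.3.  Occasional ground-truth draws
produce loop conformations whose restraint set is satisfied equally well by
distinct basins; the protocol then converges to a low-score model several
Angstrom further from the truth while the free-Q stays low -- a genuine
information limit of distance-band data, not a sampling failure, and the
reason the acceptance checks are phrased over seed medians.

## Structural analytics

`assign_secondary_structure` implements a hydrogen-bond pattern assignment
on backbone N/CA/C/O (amide H placed geometrically at 1.01 A along the
N-centered bisector when absent): the electrostatic bond energy
$E = 0.084\cdot 332\,(1/r_{ON}+1/r_{CH}-1/r_{OH}-1/r_{CN})$ kcal/mol with a
$-0.5$ cutoff, $i\to i+4$ acceptors labeling H, $i\to i+3$ labeling G,
isolated turns T, else C.  `disorder_fraction` counts T and C as disordered;
G counts as ordered (3_10 helix is drawn as helix in the field's secondary
structure figures).

`pore_profile` is a HOLE-style profiler: at each height along the symmetry
axis the in-plane center maximizing the clearance
$\min_a(|c-x_a| - r^{vdw}_a)$ is found by Nelder-Mead from the axis point
plus eight seeded perturbed starts (deterministic for a fixed seed), the
radius clamped at 15 A; step 0.5 A by default.  It deliberately does not
reproduce HOLE's Monte Carlo scheme and is documented as approximate.
`lateral_portal_radius` runs the same clearance maximization perpendicular
to a ray cast from a vestibule point on the axis through the midpoint of an
adjacent-chain interface, returning the bottleneck along the ray.
`salt_bridge_distances` reports unthresholded minimum distances between
basic side-chain nitrogens and carboxylate oxygens, intra-subunit or
minimized over the five adjacent-chain pairs.  Van der Waals radii are a
fixed Bondi-style table (`vdw_radii()`), exported because pore radii depend
on it directly.

Applied to a deposited multi-model PDB of the real receptor, these functions
reproduce the published Results-section measurements (domain height and
radius from CA distances, the two pore constrictions, the vestibule and
portal radii, the ICD disorder fraction, salt-bridge distances).  The
package does not ship that coordinate file; `read_structure` accepts a
locally downloaded copy, and measurements on ensembles report per-model
values with means (bound-type checks use the minimum over models, since the
published panels depict single representative models).

## Numerical and interface choices

* Author residue numbering is authoritative everywhere; chains are labeled
  A--E in ring order; all distances are in Angstrom.
* PDB I/O handles ATOM/HETATM/MODEL/ENDMDL/TER; highest-occupancy altloc
  kept; insertion codes rejected.  Coordinates round-trip at the format's
  fixed-width precision (1e-3 A).
* Pseudo-label sites: on reduced models the label and amide proxies resolve
  to the residue CA, and the synthetic forward models use the same
  convention, so round trips close exactly; on full-atom models the label
  site extends 3.5 A beyond CB along CA-CB (configurable).
* Restraint chain offsets are 0 (intra), 1 (adjacent), 2 (diagonal); the
  symmetric-reduced energy in the sampler (intra + adjacent + diagonal
  blocks, times five) equals the full-pentamer sum exactly for C5 models.
* All fits use deterministic initializers; every stochastic entry point
  takes an explicit seed and restores the caller's RNG state; derived seeds
  stay below $2^{31}$.
* The command-line layer (`flexfold_main`, wrapped by
  `inst/exec/flexfold`) exposes simulate / derive / protocol / qreport /
  pore / measure subcommands, writes JSON manifests with the seeds used, and
  rejects unknown options by name.

## Known limitations

* CA-only resolution: no side chains during folding, no membrane model, no
  RDC-restrained refinement (RDCs validate, they do not fold).
* The mirror degeneracy of distance-only data is broken by the template
  prior, not by the data; without a credible template the protocol returns
  both hands at equal score.
* The sigmoid PRE potential saturates a few Angstrom outside its band, so
  large violations are cheap; the flat-bottom NOE and harmonic DEER terms
  carry most of the long-range gradient.
* Bound-only restraints enter Q through violations only; a model that pushes
  every unquantifiable residue exactly to its bound is not penalized.
* The convergence rule detects score plateaus; it cannot certify global
  optimality, and one in several runs typically ends at the iteration cap
  still improving in the last window.
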