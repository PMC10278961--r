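---
title: "Methods: end-point binding free energies, PMFs, and contact networks on toy systems"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: end-point binding free energies, PMFs, and contact networks on toy systems}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bfekit)
```

bfekit implements the post-processing stack used to study how kinase
resistance mutations change inhibitor binding: end-point binding free
energies (MM/PBSA and MM/GBSA) with per-residue decomposition and
truncated normal-mode entropy, thermodynamic-integration (TI) free
energies from λ-window derivatives, umbrella-sampling potentials of mean
force (PMFs) reconstructed by WHAM, and residue contact networks built
from motion correlations. Molecular dynamics itself is out of scope: the
package consumes coordinates, biased samples, and ∂U/∂λ series, and a
seeded generator module produces all of these at bead scale with planted
ground truth so that every stage can be validated closed-loop.

This vignette records the models, their assumptions, the tunable
parameters, the numerical choices, and what the synthetic test systems
do and do not establish about behavior on real proteins.

## Units and conventions

Coordinates and cutoffs are in Å, energies in kcal/mol, charges in
elementary charges, temperatures in K, masses in amu. The Coulomb
constant is 332.0637 kcal·Å/(mol·e²) and k~B~ = 0.0019872041
kcal/(mol·K), the values used by the AMBER family of force fields that
this toy format emulates. Atom indices are 1-based everywhere, including
the on-disk topology format — R is a 1-based language and a 0-based
internal convention would invite off-by-one defects.

## The end-point model

The binding free energy is assembled per frame under the
single-trajectory protocol: complex, receptor-only, and ligand-only
energies are evaluated on the *same* coordinates and differenced,

$$\Delta G_\mathrm{bind} = \Delta H - T\Delta S, \qquad
\Delta H = \Delta E_\mathrm{ele} + \Delta E_\mathrm{vdW}
         + \Delta G_\mathrm{polar} + \Delta G_\mathrm{SA},$$

with bonded terms (bond, angle, dihedral) cancelling identically because
each bonded term lives entirely on one side of the receptor/ligand
partition. `endpoint_bfe()` computes this cancellation term-by-term —
each bonded term's complex value minus its value in the species
evaluation — so the reported residual is exactly zero in floating-point
arithmetic, not merely small; a bonded term crossing the partition is
rejected up front. Nonbonded energies use no cutoff: end-point
post-processing conventionally sums all pairs, and the MD engine's
real-space cutoff is an engine concern. 1–4 pairs are scaled by 1/1.2
(electrostatics) and 1/2 (Lennard-Jones), the AMBER defaults,
overridable in the topology file.

### Polar solvation

Two polar models are provided.

**GB (default).** A Still-type pairwise sum over OBC effective Born
radii. The descreening integrals use the exact pairwise closed form
(verified against direct numeric integration of $1/x^4$ over the
neighbor sphere), and the tanh rescaling uses α = 0.8, β = 0,
γ = 2.909125 with the 0.09 Å intrinsic-radius offset — the standard
OBC-I parameterization; the source protocol names the model but not the
constants. A single ion reduces exactly to the Born equation, which the
tests exploit as an analytic oracle.

**PB.** A finite-difference linearized Poisson–Boltzmann solver at zero
ionic strength: charges are spread trilinearly, the dielectric is
assigned per grid edge from the exact fraction of the edge inside the
union-of-spheres solute (harmonic/series averaging along the edge),
boundary potentials are analytic Coulomb sums in solvent dielectric, and
a coarse-then-fine focusing pass refines the solute region. The linear
system is solved by Jacobi-preconditioned conjugate gradients. The
reaction-field energy is ½Σqφ differenced against a uniform-dielectric
reference solve on the identical grid, which cancels the grid
self-energy. On the Born ion the solver converges monotonically (2.9%,
0.54%, 0.11% relative error at 1.0, 0.5, 0.25 Å spacing) and matches the
Kirkwood series for an off-center charge in a spherical cavity to ~0.1%.
Cavity radii default to the per-atom GB radii; the original protocol's
PB radii set is cited but not reproduced there, so the package uses its
own documented radius source and says so.

The solute dielectric ε~in~ defaults to 1 and may be set to 2 or 4 (the
protocol's comparison grid); ε~out~ = 80.

### Nonpolar solvation

$\Delta G_\mathrm{SA} = \gamma\,\mathrm{SASA} + b$ with γ = 0.0072
kcal/(mol·Å²) and b = 0. SASA uses the LCPO pairwise-overlap
approximation with parameters keyed by element and bonded heavy-atom
count (free atoms use the exact-sphere entry, so an isolated sphere is
analytic; unparameterized types fall back to a generic sp³-carbon entry
with a warning). A deterministic Shrake–Rupley implementation
(golden-spiral points) serves as the numeric reference; on random bead
chains LCPO tracks it within ~6%, and fully coincident spheres — outside
the regime LCPO was fitted for — stay within ~35%. The probe radius is
1.4 Å (standard water probe). Hydrogens carry no surface, matching the
convention of the parameter set.

### Entropy

`nme_binding_entropy()` estimates $-T\Delta S$ by normal-mode analysis
on frames extracted at equal intervals. The complex is first truncated:
every receptor residue with any *heavy* atom within 9 Å of any ligand
heavy atom is kept whole (the hydrogens-excluded reading follows the
protocol's "heavy atoms" phrasing). Residues left without a sequence
neighbor are recorded as discontinuous termini in metadata; bead systems
need no chemical caps, and the charged-group capping used on real
proteins is acknowledged as a fidelity gap. Each species is minimized
(steepest-descent warm-up, one conjugate-gradient cycle, then repeated
BFGS restarts — a single CG cycle stalls in the shallow valleys of the
toy landscape) to an RMS gradient of 1e-4 kcal/(mol·Å) with a 10,000-step
budget, both protocol defaults. The Hessian is built by central
differences of the analytic gradient, mass-weighted with standard atomic
masses, and 6 external modes are removed (5 for linear geometries, 3 for
single atoms) — the mode count is not stated by the protocol and is the
standard choice. Vibrational entropy uses the harmonic-oscillator
formula; rigid-rotor and ideal-gas (1 atm) translational terms complete
the per-species entropy. A diatomic with known stretch frequency
reproduces the closed-form oscillator entropy to machine precision.

### Decomposition

`per_residue_decomposition()` splits every ligand–receptor pair energy
half/half between the two residues; GB polar terms are decomposed
pairwise the same way (self terms stay with their residue), and nonpolar
terms are assigned per atom from the per-atom SASA change. Sums over
residues reconstruct the complex totals to ≤1e-6 kcal/mol (observed:
~1e-15). Under the PB model the polar column still uses the GB pairwise
form — finite-difference PB is not pairwise decomposable — and the
function says so; PB enters totals only. This is the standard practice
trade-off. ΔΔG tables (mutant minus wild type, positive = resistance)
follow from differencing two runs.

## Thermodynamic integration

`trapezoid_integrate()` implements the trapezoidal (TRA) estimator over
per-window sample means on a λ grid that must include both endpoints;
the default grid is the 14-point schedule (0, 0.0001, 0.001, 0.01, 0.1,
…, 1.0), dense near λ = 0 where softcore-decoupled derivatives vary
fastest. Only TRA is implemented; Gaussian-quadrature and
Bennett-family estimators are deliberate non-goals. Window means use all
samples by default with an optional equilibration-discard fraction
(default 0 — the source protocol states none). `replica_statistics()`
averages replicas (sample SD, n−1); `ddg_cycle()` closes the
double-decoupling cycle with ΔΔG = ΔG~holo~ − ΔG~apo~, positive meaning
weakened binding. The sign mapping onto any particular published TI
table is a convention choice, documented rather than asserted.

## Umbrella sampling and WHAM

The harmonic bias is $w_i(\xi) = \tfrac{K}{2}(\xi - \xi_i^{ref})^2$. The
default layout is 41 restraint centers spaced 0.5 Å spanning 12.5–32.5 Å
inclusive with K = 5 kcal/(mol·Å²); "a restraint in the middle of each
window" is read so that the 41 centers cover the stated range
end-to-end. `wham()` iterates the self-consistent equations on the
window offsets to 1e-6 kcal/mol (cap 100,000 iterations), using 0.1 Å
bins — five bins per window width, balancing resolution against counts.
The unbiased probability is normalized to unit mass before the log
transform; empty interior bins are masked and reported; profiles are
anchored to min = 0. With one effectively unbiased window WHAM reduces
exactly to −k~B~T·log(histogram). `average_pmf()` re-anchors and
averages the trailing `last_n` rounds (default 10 of 18, the
convergence-declaration recipe), and `pmf_delta()` reports
bulk-mean-minus-bound-minimum. Profile comparisons in the tests use RMSD
after the optimal constant shift, since free-energy profiles are defined
up to an additive constant.

The reaction coordinate is a generic scalar; its physical definition
(a receptor-atom-to-ligand-atom distance in the source system) lives in
the generator, not the estimator.

## Contact network analysis

Nodes are one designated atom per residue (Cα-like). Correlations
$C_{ij}$ come from mean-centered displacement dot products after
superposing all frames onto the mean structure (one refit iteration);
edge weights are $d_{ij} = -\log|C_{ij}|$ with the natural logarithm
(the source writes "log" without a base) and $|C_{ij}|$ floored at
1e-12. Negative correlations enter through their absolute value — the
weight formula is undefined for $C \le 0$ — and are flagged on the edge.

Adjacency uses the standard dynamical-network convention: residues are
in contact when their any-heavy-atom minimum distance is ≤ 4.5 Å in at
least 75% of frames. The literal reading (Cα atoms themselves within
4.5 Å) is geometrically too strict for spatial neighbors but is
available as `calpha_strict = TRUE`. Girvan–Newman community detection
removes maximum-betweenness edges (weights as distances, via igraph) and
selects the partition maximizing unweighted modularity over the
dendrogram, ties resolving to the coarsest partition; using
$|C|$-weighted modularity was evaluated and recovered planted
communities less reliably on sparse toy graphs, so the unweighted form
is the default. Optimal and k-suboptimal communication paths are
shortest paths on $d_{ij}$. Hydrogen bonds use donor-heavy-to-acceptor
distance ≤ 3.0 Å and donor–H···acceptor angle ≥ 135°, the defaults of
the conventional trajectory-analysis tools.

## The synthetic study systems

`make_toy_complex()` builds a ring of 3-bead residues around a small
ligand cluster, fully parameterized with narrow physical ranges (bond k
200–400 kcal/mol/Å², |q| ≤ 0.45 e, R~min~/2 1.6–2.0 Å) chosen to keep
normal-mode analysis well-conditioned. One pocket residue is a planted
mutation site whose bead charge flips sign between wild type and mutant,
emulating the direct electrostatic clash of an in-pocket resistance
mutation; the mutant's ligand–receptor electrostatics are verifiably
less favorable. `make_correlated_trajectory()` plants communities as
compact per-group clusters sharing a latent displacement; clusters
(rather than chains) give the dense intra-group contact structure that
packed protein domains actually have, and recovery through the full
correlation → network → community pipeline was verified perfect over 60
seed/shape combinations. `make_umbrella_dataset()` samples each window
by Metropolis (step auto-tuned to 30–50% acceptance, 10% burn-in
discarded) from a known PMF, optionally adding a per-round decaying
drift to emulate slow equilibration across rounds.
`make_ti_dataset()` adds Gaussian noise to a known ⟨∂U/∂λ⟩ curve;
`make_benchmark_pairs()` draws bivariate-normal experiment/prediction
pairs at a requested correlation. All generators restore the caller's
RNG state and are bit-reproducible under a seed.

What passing these tests shows: the estimators are implemented
correctly — they recover planted truths at the statistical precision the
sample sizes allow, reduce to analytic results in the solvable limits,
and conserve what they should conserve. What they do not show: force
fields, sampling adequacy, or solvation parameterizations appropriate to
real proteins; bead systems have no secondary structure, water, or
protonation chemistry, and entropy truncation on real systems involves
capping chemistry that toy systems cannot exercise.

## Problem sizes and defaults

The shipped tests and the acceptance script use desk-scale sizes chosen
as this package's own study conditions: toy complexes of ~8 residues ×
3 beads + a 5-bead ligand; 41 umbrella windows × 1,000 samples (one
round) or × 400 samples (18 rounds) — the per-window sample count maps
one sample per ps of the 1-ns windows of the reference protocol; TI with
5 replicas × 14 λ × 1,000 samples; community plants of 2–3 groups × 5–6
residues over 80–120 frames; PB grids at 0.5 Å with focusing (0.25 Å in
the refinement study). A full suite run takes under a minute on one CPU.

## Known limitations

- PB per-residue decomposition is delegated to the GB pairwise form.
- The PB dielectric edge fraction uses the maximum over atoms rather
  than the exact union length when an edge crosses several spheres; the
  cases differ only for deeply overlapping spheres.
- LCPO parameters cover C/N/O/S/P with common bonded counts; exotic
  types fall back with a warning.
- Entropy truncation records discontinuous termini but does not
  chemically cap them.
- `optimal_path()` suboptimal paths are Yen k-shortest simple paths;
  no within-offset exhaustive enumeration.
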