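# bfekit

Binding free energies, PMFs, and contact networks for studying how
mutations change small-molecule binding — the post-processing stack
behind drug-resistance analyses of kinase inhibitors, implemented as a
tested, reusable R package that runs end-to-end on synthetic toy
systems.

Resistance mutations weaken inhibitor binding either directly (an
in-pocket clash) or through long allosteric chains. Quantifying either
mechanism from simulation needs four tool families, all provided here:

- **End-point binding free energies** (`endpoint_bfe()`): the
  MM/PB(GB)SA model under the single-trajectory protocol,

  ΔG_bind = ΔH − TΔS,  ΔH = ΔE_ele + ΔE_vdW + ΔG_polar + ΔG_SA,

  with exact cancellation of bonded terms, OBC generalized-Born or
  finite-difference Poisson–Boltzmann polar solvation, LCPO surface
  areas (ΔG_SA = γ·SASA + b, γ = 0.0072 kcal/(mol·Å²), b = 0),
  per-residue decomposition (`per_residue_decomposition()`), and
  truncated normal-mode entropy (`nme_binding_entropy()`, 9-Å
  whole-residue truncation).
- **Thermodynamic integration** (`trapezoid_integrate()`,
  `replica_statistics()`, `ddg_cycle()`): the trapezoidal estimator of
  ΔG = ∫₀¹ ⟨∂U/∂λ⟩ dλ on a 14-λ schedule with replica statistics and
  double-decoupling ΔΔG cycles.
- **Umbrella sampling → WHAM** (`wham()`, `average_pmf()`,
  `pmf_delta()`): self-consistent reweighting of harmonically biased
  windows (41 windows, 0.5 Å, K = 5 kcal/(mol·Å²) by default) into a
  potential of mean force, with trailing-round averaging.
- **Contact network analysis** (`displacement_correlation()`,
  `build_network()`, `girvan_newman()`, `optimal_path()`,
  `hbond_occupancy()`): residue graphs with edge weights
  d_ij = −log|C_ij| from motion correlations, 4.5-Å/75%-occupancy
  contacts, Girvan–Newman communities, shortest transmission paths, and
  hydrogen-bond occupancies.

A first-class generator module (`make_toy_complex()`,
`make_correlated_trajectory()`, `make_umbrella_dataset()`,
`make_ti_dataset()`, `make_benchmark_pairs()`) produces every input the
pipeline consumes, seeded and with planted ground truth, so the whole
stack is testable without any molecular-dynamics engine. Results are
tibbles with `tidy()`/`glance()`/`autoplot()` methods.

## Worked example

Score a wild-type/mutant pair of toy complexes with MM/GBSA and check a
TI dataset against its planted integral:

```r
library(bfekit)

toy_wt  <- make_toy_complex(seed = 42)
toy_mut <- make_toy_complex(seed = 42, mutate = TRUE)
cfg <- solvation_config("GB")
res_wt <- endpoint_bfe(toy_wt$system, toy_wt$frame, cfg)
res_wt
#> <endpoint_result> MM/GBSA, eps_in = 1, 1 frame(s)
#>   ele         -16.1054 +/- NA kcal/mol
#>   vdw          -2.1322 +/- NA kcal/mol
#>   bonded        0.0000 +/- NA kcal/mol
#>   polar        16.2564 +/- NA kcal/mol
#>   nonpolar     -1.5906 +/- NA kcal/mol
#>   dh           -3.5718 +/- NA kcal/mol
#>   dG_bind      -3.5718 kcal/mol

res_mut <- endpoint_bfe(toy_mut$system, toy_mut$frame, cfg)
delta_delta_g(res_mut, res_wt)
#> [1] 0.4917055
```

The favorable electrostatics (−16.1) are largely offset by polar
desolvation (+16.3), leaving a net ΔH of −3.6 kcal/mol; the planted
in-pocket mutation weakens binding by ~0.5 kcal/mol (positive ΔΔG =
resistance, partially compensated by solvation — flip the charge, pay
less desolvation).

```r
ti <- make_ti_dataset(seed = 1)       # 5 replicas x 14 lambda windows
replica_statistics(ti)
#> <ti_result> 5 replica(s), 14 lambda windows
#>   dG = 1.0025 +/- 0.0102 kcal/mol
attr(ti, "truth")
#> [1] 1
```

The noisy 5-replica estimate recovers the planted integral (1.0025 vs
1) within its replica spread.

A thin CLI wraps the same functions
(`Rscript inst/cli/bfekit.R <simulate|endpoint|ti|wham|cna|hbond|bench> ...`),
and `run_demo_pipeline(dir, seed)` writes a deterministic end-to-end set
of result tables.

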