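---
title: "Benchmarking conformer generators: models, parameters and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking conformer generators: models, parameters and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(confbench)
```

# The evaluation model

A benchmarking study compares several conformational-search methods on a
set of catalysts against one designated reference method. Each
(catalyst, method) pair contributes one *ensemble*: an ordered list of
conformers sharing atom count and element ordering, each with Cartesian
coordinates (Å) and an energy (kcal/mol on the producing method's own
scale). Five 0–10 grades are computed per method:

1. **Prediction capacity** = 10 · n_correct / N. A catalyst counts as
   correct when the method's minimum-energy conformer matches the
   reference's minimum-energy conformer geometrically: representative-atom
   Kabsch RMSD at most `match_threshold` (default 0.5 Å, the same scale
   used for RMSD deduplication). The threshold is configurable because
   "same conformer" is a resolution-dependent judgement.
2. **Tunability** = 10 · n_features / 7, counting which of seven features
   a program lets the user modify (optimization method, generation
   method, cutoffs, molecular charge, constraints, solvent, temperature).
   Only whole features count; fractional credit is rejected.
3. **Exploration** = 10 · mean over catalysts of the method's cluster
   participation (clusters containing at least one of its conformers,
   over all clusters found for that catalyst). Averaging per-catalyst
   fractions — rather than pooling counts — weights every catalyst
   equally regardless of how many clusters it produces, matching the
   grade's per-catalyst definition.
4. **Structural accuracy**: the mean representative-atom RMSD between a
   method's conformers and their reference-optimized counterparts, mapped
   linearly from 0 Å (grade 10) to 4.70 Å (grade 0) and clipped below at
   0. The two anchors are the published calibration of this scale; linear
   interpolation is the minimal assumption connecting them.
5. **Energy accuracy**: the RMSD between paired *relative* energy vectors
   (each shifted to its own minimum), mapped linearly from 0 (grade 10)
   to 17.31 kcal/mol (grade 0), clipped at 0. Relative energies are
   essential: force-field, semiempirical and DFT absolute scales are
   incommensurable. In the energy criterion the pair count plays the role
   the atom count plays in the structural one; the pairing is by
   conformer identity, never by rank.

## Representative atoms and dihedrals

All geometric comparisons are restricted to a per-catalyst
*representative selection*: a hand-picked set of scaffold/substituent
atoms and bonded dihedral quadruples that keeps conformers
distinguishable while avoiding local-symmetry artifacts (equivalent aryl
positions, rotor permutations) and needless cost. Subset RMSD uses Kabsch
superposition — centering both point sets and taking the SVD-optimal
proper rotation — because conformers from different programs arrive in
arbitrary frames; without superposition the "structural" criterion would
measure frame placement. **All atom indices in this package are
1-based**, following R convention.

# Pooled clustering

Per catalyst, the non-reference ensembles are pooled and a pairwise
distance matrix is computed with the `blended` metric: the circular
root-mean-square torsion difference (each difference wrapped to
[0, 180]°) and the subset RMSD matrix are each normalized by their own
maximum and mixed with weight `w` (default 0.5). Torsions and subset RMSD
carry complementary information (topology of rotors vs actual shape);
the blend uses both without letting either unit dominate. `w` is exposed
in the configuration.

**Embedding.** `embed_2d()` is a deterministic neighborhood-graph
embedding of the precomputed distance matrix: a symmetric k-nearest-
neighbor graph (`n_neighbors`, default 15) is built, geodesic distances
are computed within each connected component, each component is laid out
by classical multidimensional scaling of its geodesics, and disconnected
components — the signature of well-separated basins — are placed on a
grid whose spacing exceeds every component diameter scaled by
`1 + min_distance` (default `min_distance = 0.1`). Separated basins
therefore remain separated in 2-D by construction, which is the
qualitative behavior nonlinear manifold learners exhibit on disconnected
data, here obtained without stochastic optimization. `random_state`
(default 42) is recorded in every manifest for provenance but the
algorithm is exactly reproducible regardless of it.

**Density clustering.** `density_cluster()` follows the HDBSCAN
construction: core distances at neighbor rank `min_samples` (default 5),
mutual-reachability distances, a minimum spanning tree, the
single-linkage hierarchy, condensation with `min_cluster_size` (default
8), and excess-of-mass cluster selection. Points that never join a
selected cluster are outliers (label −1); outliers are reported but
excluded from both the numerator and denominator of participation.
Defaults replace per-dataset manual tweaking so runs are reproducible;
both parameters accept per-study overrides in the configuration.

Numerical/degenerate-input choices:

* zero-height merges use λ = 1/max(h, 1e−12);
* if every point is coincident, one cluster is returned directly (the
  condensed tree has no true splits, so selection would otherwise return
  all-noise for an input that is plainly one cluster);
* the hierarchy root is never selectable, so structureless sparse data
  with a large `min_cluster_size` correctly comes back all-noise, with a
  warning when there are fewer points than `min_cluster_size`;
* cluster labels are relabeled contiguously (0 … k−1) by first member
  index, making labels independent of internal processing order.

# Filtration rules

* `energy_window_filter(e, cutoff)` keeps conformers with relative energy
  ≤ cutoff (inclusive boundaries throughout; common settings are 10
  kcal/mol for unconstrained searches, 20 for constrained ones, 6 for
  metadynamics ensembles). The global minimum always survives.
* `rmsd_dedupe(e, rmsd_threshold, sel, energy_threshold)` makes a single
  greedy pass in ascending energy order, dropping a conformer lying
  within `rmsd_threshold` of an already-kept one — and, when
  `energy_threshold` is supplied (pair-merging rule, e.g. 0.125 Å with
  0.05 kcal/mol), only when *both* gates fire. Ascending-energy order is
  a deliberate choice: it guarantees the global minimum is kept, matching
  how search programs report their best conformer, and makes the pass
  deterministic (ties broken by original index).
* `diversity_subset(e, k, sel)` is greedy max–min dispersion seeded at
  the lowest-energy conformer, ties to the lower index. Greedy max–min
  carries the classical factor-2 dispersion guarantee and is exactly
  optimal on one-dimensional "ladder" instances; it is the declared
  stand-in for manually picking "as different as possible" structures
  ahead of expensive re-optimization, and `k = 10` per catalyst is the
  default accuracy-pair protocol.
* `suggested_conformer_count(n)` is the nr³ sizing heuristic for
  knowledge-based embedding.

# Boltzmann populations

Weights are w_i = exp(−ΔE_i/RT)/Σ_j exp(−ΔE_j/RT) with
R = 1.987204×10⁻³ kcal/(mol·K) and T = 298 K by default (overridable);
energies are shifted by their minimum before exponentiation, so weights
are stable for arbitrary spans and invariant under additive shifts. No
free-energy corrections (ZPE, entropy) are applied — the statistic
weights bare relative energies. The coverage fraction ranks conformers by
descending weight (ties by index) and returns m/n for the smallest head
reaching a cumulative population q (default 0.99, compared with ≥); the
population histogram groups ranked conformers into 5% rank intervals.

# The synthetic study generator

A synthetic "catalyst" is a chain molecule (bond 1.5 Å, angle 109.5°)
whose conformational space is a declared set of torsion basins, each a
center vector plus a well energy; within-basin spread is wrapped-Gaussian
torsion jitter (respecting periodicity). A synthetic "method" samples a
subset of basins (`basin_coverage`), perturbs coordinates with Gaussian
noise (`geometric_jitter_sigma`, Å) and energies with Gaussian error
(`energy_error_sigma`, kcal/mol) plus an optional per-basin bias. A
"constrained" search is emulated by freezing one dihedral across all
basins. Chain geometries are built by natural extension of the reference
frame; the measured dihedral on quad (i, i+1, i+2, i+3) reproduces the
requested torsion to below 1e−6°, verified by property tests. Every
(sampler, catalyst) pair gets its own derived seed, so studies are
reproducible element-wise.

The default study uses 3 catalysts with 6 basins each (centers 60° apart
in every backbone torsion — far beyond the 5× separability requirement at
5° jitter; wells 0–5 kcal/mol in 1 kcal/mol steps), four samplers with
coverages 6/5/4/3, noise 0.02 Å and 0.3 kcal/mol, and a noise-free
reference. **Sizes were chosen once**: 20 samples per covered basin keeps
the smallest single-method basin above the default 15-point embedding
neighborhood (so basins disconnect cleanly in the k-NN graph) while the
pooled 360-conformer matrices stay comfortable on a single CPU; 3
catalysts exercise the per-catalyst averaging without redundancy.

What the generator emulates: coverage differences between search
algorithms, geometric optimization noise, energy-ranking error, basin
multiplicity, constrained searches. What it does not: real force-field
energy landscapes (energies are declarative labels), anharmonic basin
shapes, correlated errors between geometry and energy, symmetry-related
minima, and molecules with more than one rotor chain. Passing recovery
tests therefore demonstrate that the *pipeline statistics* are computed
correctly and are sensitive to the planted signal — not that any
particular real search program would receive these grades.

# Known limitations

* **Energy-accuracy anchoring.** Because each relative-energy vector is
  anchored at its own minimum, a method with iid energy error σ carries a
  systematic offset equal to the extreme order statistic of its errors:
  with many samples the measured energy RMSD concentrates near
  σ·√(1 + 2.25²) ≈ 2.4σ rather than σ. This is an intrinsic property of
  min-anchored relative energies (the grading formula inherits it), not
  an implementation artifact; comparisons between methods remain fair
  because all methods are anchored the same way.
* Greedy max–min diversity selection is a 2-approximation; for k ≥ 3 on
  adversarial geometries it can miss the exhaustive optimum.
* The embedding is exact on disconnected neighborhood graphs but, like
  any 2-D projection, can fold a single connected component with more
  than two intrinsic dimensions.
* Cluster counts depend on `min_cluster_size`/`min_samples` as in any
  density-based method; the defaults suit basin sizes of ~10 and larger.
* SDF connectivity is not benchmarked: the writer emits a sequential
  chain bond block (exact for synthetic chains, a placeholder otherwise).

# Orchestration and provenance

`run_study()` validates its configuration (field-path error messages),
runs clustering, population and grading, and writes TSV tables plus a
JSON manifest recording the configuration, seed, package version and
ensemble sizes, so every number in the report traces back to inputs and
parameters. Reruns with the same configuration and seed produce
byte-identical tables; per-catalyst cluster outputs can be reused with
`resume = TRUE`. The `analysis/` scripts wrap the same functions as a
narrative workflow.
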