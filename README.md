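# confbench

Benchmarking conformer-ensemble generators against a reference method.

## The problem

Conformational-search programs (genetic-algorithm embedders,
knowledge-based embedding, systematic dihedral scans, metadynamics) differ
wildly in how much of a flexible molecule's torsional space they explore,
how faithfully they rank conformers energetically, and how close their
optimized geometries come to a high-level reference. For flexible
organocatalysts — e.g. Cinchona-alkaloid phase-transfer catalysts, whose
activity hinges on which amide rotamer the search finds — picking the
wrong search tool silently biases everything downstream.

`confbench` implements a complete, tested evaluation pipeline for such
comparisons, for computational chemists who want to score search methods
on their own systems (or on ground-truthed synthetic ones):

* **I/O** — multi-record V2000 SDF and multi-frame XYZ ensembles with
  per-conformer energies (kcal/mol; optional hartree conversion at
  627.509 kcal/mol per hartree). Atom indices are **1-based** everywhere.
* **Geometry** — Kabsch superposition RMSD on representative-atom subsets,
  IUPAC signed dihedrals, torsion feature vectors, and pairwise distance
  matrices (subset RMSD, circular torsion RMS, or a blended metric).
* **Filtration** — energy windows (`energy_window_filter`), greedy RMSD
  deduplication with an optional pair-energy gate (`rmsd_dedupe`), max–min
  diversity selection (`diversity_subset`), and the nr³ sizing heuristic.
* **Population** — Boltzmann weights at 298 K
  (w_i = exp(−ΔE_i/RT)/Σ_j exp(−ΔE_j/RT)), 99%-population coverage
  fractions, and 5%-interval population histograms.
* **Clustering** — per catalyst, all methods' conformers are pooled,
  embedded to 2-D from the precomputed distance matrix and
  density-clustered (an in-package HDBSCAN: mutual-reachability MST,
  condensed tree, excess-of-mass selection, outliers labeled −1), giving
  cluster composition tables and per-method participation fractions.
* **Grading** — five 0–10 criteria per method:
  * prediction capacity: 10 · n_correct / N over N catalysts,
  * tunability: 10 · n_features / 7 over the seven-feature checklist,
  * exploration: 10 · mean per-catalyst cluster participation,
  * structural accuracy: linear from RMSD 0 Å (grade 10) to 4.70 Å (grade 0),
  * energy accuracy: linear from 0 (grade 10) to 17.31 kcal/mol (grade 0).
* **Synthetic studies** — torsion-landscape "catalysts" with known basins
  sampled by simulated "methods" with controlled coverage, geometric
  jitter and energy error, so every statistic can be checked against
  ground truth.

## Worked example

The `analysis/` scripts run the whole workflow on the default synthetic
study (3 catalysts × 6 torsion basins, four samplers covering 6/5/4/3
basins, 20 conformers per covered basin, plus a noise-free reference):

```sh
Rscript analysis/01_simulate.R    # write SDF/XYZ ensembles + ground truth
Rscript analysis/02_cluster.R     # pooled clustering + participation
Rscript analysis/03_population.R  # Boltzmann population summaries
Rscript analysis/04_grade.R       # the five-criterion grade report
```

Step 2 prints, for every catalyst (here `cat_03`):

```
cat_03: 6 clusters, 0 outliers (true basin count 6)
  metaMD       participates in  6 / 6 clusters (1.000); true coverage 6/6
  systematic   participates in  5 / 6 clusters (0.833); true coverage 5/6
  knowledge    participates in  4 / 6 clusters (0.667); true coverage 4/6
  genetic      participates in  3 / 6 clusters (0.500); true coverage 3/6
```

i.e. the pipeline recovers exactly the six planted basins and each
sampler's participation equals its true basin coverage. Step 4 compiles
the grades:

```
      method grade_prediction grade_tunability grade_exploration grade_structure grade_energy
1     metaMD               10        10.000000         10.000000        9.629639     9.619405
2 systematic               10         4.285714          8.333333        9.625260     9.732592
3  knowledge               10         7.142857          6.666667        9.637638     9.618484
4    genetic               10         5.714286          5.000000        9.678360     9.597995
```

All four samplers find the reference's most stable conformer (prediction
10); exploration grades are exactly 10 × coverage/6; structural grades sit
near 9.6 because 5° torsion jitter plus 0.02 Å Cartesian noise amounts to
a ~0.17 Å mean representative-atom RMSD on the 4.70 Å calibration scale;
energy grades near 9.6 reflect the 0.3 kcal/mol injected energy error on
the 17.31 kcal/mol scale. The same computations are available
programmatically via `run_study(default_config(seed = 1), out_dir)`.

## Package layout

* `R/` — all computation (I/O, geometry, filtration, population,
  clustering, grading, synthetic studies, orchestration).
* `analysis/` — the numbered workflow drivers shown above.
* `tests/testthat/` — unit, property and end-to-end recovery tests.
* `vignettes/confbench-methods.Rmd` — models, parameters, numerical
  choices and limitations.
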