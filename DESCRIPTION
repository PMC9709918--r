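Package: confbench
Title: Benchmarking Conformer-Ensemble Generators Against a Reference Method
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evaluating conformational-search programs against a
    reference ensemble: representative-atom Kabsch RMSD and torsion-angle
    featurization, energy-window and RMSD filtration of conformer sets,
    Boltzmann population summaries, pooled-ensemble 2-D embedding and
    density-based clustering with per-method cluster participation, and a
    five-criterion 0-10 grading scheme (prediction capacity, tunability,
    conformational-space exploration, structural accuracy, energy accuracy).
    Includes a synthetic torsion-landscape study generator with known ground
    truth so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    jsonlite,
    yaml,
    ChemmineR
Suggests:
    testthat (>= 3.0.0),
    bio3d,
    mclust,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
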