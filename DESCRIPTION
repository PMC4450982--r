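Package: procbench
Title: Evaluation of Structure-Based Virtual Screening Benchmarks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Post-docking evaluation toolkit for structure-based virtual
    screening benchmarks built from bioactives and property-matched decoys
    (DEKOIS-style sets). Computes semi-logarithmic ROC enrichment (pROC-AUC)
    with early-recognition emphasis, compares ligand/target preparation
    schemes with a significance safety margin, normalizes docking scores by
    heavy-atom count, runs protomer shuffling, deletion and match/mismatch
    experiments, audits paired ligand preparations for protonation, tautomer
    and ring-conformation differences (including symmetry-aware RMSD), and
    generates synthetic benchmarks with known ground truth for testing the
    whole pipeline without docking software.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    yaml,
    withr,
    igraph,
    ChemmineR,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
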