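Package: topobind
Title: Interpretable Protein-Ligand Binding Prediction with Bipartite
    Persistent Homology
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes internuclear persistence contours (IPCs) of
    protein-ligand complexes from the Vietoris-Rips filtration under the
    opposition distance (Euclidean across the protein/ligand bipartition,
    infinite within a side), discretizes them into binned densities, and
    reduces them to a 10-component persistence fingerprint. Ships a small
    interpretable gradient-boosted regression-tree learner for binding
    affinity regression on fingerprints and binder/decoy scoring on
    radius-truncated IPC stacks, with mean-decrease-in-impurity feature
    selection, human-readable model export, per-atom attribution of
    predictions, and a provably tight radius-truncation approximation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    jsonlite,
    ggplot2,
    generics,
    bio3d,
    pROC,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    rpart,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
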