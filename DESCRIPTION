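Package: bfekit
Title: Toy-Scale Binding Free Energy, PMF, and Contact-Network Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.com",
           role = c("aut", "cre"))
Description: End-point binding free energy analysis (MM/PBSA and MM/GBSA) with
    per-residue energy decomposition and truncated normal-mode entropy,
    thermodynamic-integration free energies from lambda-window derivatives,
    umbrella-sampling potentials of mean force via the weighted histogram
    analysis method, and correlation-based residue contact-network analysis
    with Girvan-Newman community detection. All stages operate on small,
    fully parameterized toy molecular systems; seeded generators produce
    every input with planted ground truth so the whole pipeline is testable
    end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
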