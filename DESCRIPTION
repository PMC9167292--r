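Package: abdyn
Title: Domain-Level Analysis of Antibody Internal Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analyzes the internal dynamics of IgG-class antibodies from
    molecular-dynamics trajectories using a six-bead domain coarse-graining.
    Computes inter-domain distance, angle and dihedral observables, hydrogen-bond
    occupancy and persistence across replicates, Fc-aligned essential-dynamics
    principal component analysis with per-atom and per-fragment attributions,
    and the external work of a constant-force pulling assay. Ships a synthetic
    trajectory generator (rigid-domain motion with planted observable statistics,
    programmable hydrogen-bond schedules, and an overdamped Langevin toy model
    with a breakable inter-domain well) so every stage of the pipeline can be
    validated against known ground truth, including the Jarzynski bound on
    pulling work.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    nortest,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
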