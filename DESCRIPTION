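Package: hydronet
Title: Hydrogen-Bond Water Network Analysis Across Protein Structures
    and Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds hydrogen-bond graphs over crystallographic and
    simulation waters (and their protein partners), computes graph
    metrics (density, degree entropy, characteristic path length,
    clustering coefficients, connected components), and quantifies
    cross-structure conservation of water positions via density-based
    clustering of pooled water oxygens, a crowding-normalised
    conservation score, per-residue water interaction scores, and a
    two-reference-angle classification of water-protein contacts.
    Structures are placed on a common footing by a built-in progressive
    multiple sequence alignment (or an imported PIR/FASTA alignment)
    and Kabsch superposition. Includes a synthetic-fixture generator
    with planted water sites for validation, exporters for PyMOL,
    OpenDX and CSV, and a pipeline driver with a YAML configuration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    RANN,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
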