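Package: baitring
Title: Circular Bait-Prey Interaction Diagrams for AP-MS Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds publication-quality circular diagrams of affinity
    purification mass spectrometry (AP-MS) experiments. A single bait
    protein and its classed interactions (protein-protein interactions
    drawn as colored arcs, in vitro kinase substrates as black arcs) are
    projected onto a reference of named, functionally annotated protein
    sets laid out proportionally around a ring, with redundant or
    non-redundant occurrence mapping. Parses the three comma-delimited
    input dialects (experiment, FASTA-like set reference, RGB color
    scheme), computes a renderer-agnostic angular scene, and exports
    deterministic SVG and PDF vector graphics. Includes a seeded
    synthetic fixture generator and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    grDevices,
    grid,
    jsonlite,
    purrr,
    rlang,
    tibble,
    tools
Suggests:
    testthat (>= 3.0.0),
    xml2
Config/testthat/edition: 3
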