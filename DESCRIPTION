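Package: scaffpatch
Title: Mutable Surface Patch Detection and NNK Library Design for Protein Scaffolds
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A systematic in-silico workflow for selecting small non-antibody
    protein scaffolds for directed evolution. Filters Protein Data Bank
    candidates by size, resolution, oligomeric state and cysteine content;
    computes per-residue evolutionary conservation from multiple sequence
    alignments and mutability scores from saturation-mutagenesis ddG tables;
    detects and completes spatially contiguous mutable surface patches via a
    residue contact graph on Shrake-Rupley solvent accessibility; designs
    degenerate-codon (NNK) DNA libraries with exact diversity statistics and a
    ribosome-display cassette layout; and verifies fold retention of evolved
    variants by Kabsch superposition. Includes seeded synthetic-data
    generators (structures, alignments, ddG matrices) with planted ground
    truth so the whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    Biostrings,
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
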