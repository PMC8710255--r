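Package: regsp
Title: Multi-Reference Homology-Based Gene Search and Dot-Plot Visualisation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Homology-based gene search in assembled contigs against multiple
    reference organellar genomes. BLASTx-style high-scoring segment pairs are
    grouped by query-interval overlap, capped per group at N-1 hits by score,
    and contigs are validated by a minimum sub-gene count M; results are
    written as sorted plain-text gene reports. Nucleotide similarity between
    query contigs and each reference is computed by exact k-mer matching on
    both strands, merged into diagonal segments, and drawn as a multi-panel
    dot plot with forward/reverse orientation colouring. Includes a
    dependency-free translated search (six-frame translation, exact peptide
    seeding, ungapped x-drop extension) as a built-in HSP source, a synthetic
    genome/contig simulator for validation, and a command-line driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    S4Vectors,
    jsonlite,
    grDevices,
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
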