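Package: tapewriter
Title: Sequential Genome-Editing Tape Simulation, Parsing and Lineage Reconstruction
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Computational stack for insertional molecular recorders built on
    tandem arrays of truncated CRISPR target monomers ("DNA Tape"), where each
    prime-editing insertion writes a short barcode and activates the next
    monomer so that edits accrue strictly sequentially. Provides generative
    simulators of multi-epoch transfection programmes and of recording during
    clonal expansion; exact rendering and parsing of tape amplicons with
    editing metrics and count-based barcode whitelisting; temporal ordering of
    recorded events from site unigram and adjacent-site bigram statistics; a
    Base64-style text codec over 3-nt insertion barcodes; and order-aware
    lineage reconstruction from single-cell tape tables (prefix-qualified
    shared-edit distances, UPGMA and neighbour-joining trees, Fitch parsimony,
    tape-block bootstrap), plus file formats and a subcommand CLI binding the
    stages into reproducible pipelines.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    data.table,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
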