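Package: homorun
Title: Homopolymer Run Spectra, Shuffle Null Models and Slippage Hotspot
    Attribution in Coding Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decomposes nucleotide sequences into maximal homopolymer runs and
    builds run-length spectra, compares observed spectra against a
    composition-preserving nucleotide-shuffle null model (Monte Carlo, exact
    permutation enumeration, and an i.i.d. closed form), computes between-group
    homopolymer enrichment ratios, filters deep-sequencing variant calls by
    allele frequency and Fisher strand balance, attributes indel variants to
    homopolymer runs to rank slippage hotspots, normalizes integron cassette
    array maps, and simulates integrase-like genes and slippage-driven variant
    tables with known ground truth so every stage is testable without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils,
    vcfR
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
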