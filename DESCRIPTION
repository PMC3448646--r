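Package: v4barcode
Title: Distance and Character-Based DNA Barcoding with the 18S V4 Region
Version: 0.1.0
Authors@R: person("Ian", "Drummond", email = "idrummond@example.org",
    role = c("aut", "cre"))
Description: Tools for evaluating short hypervariable rDNA regions (such as
    the 18S V4 region amplified by the D512/D978 primer pair) as DNA
    barcodes. Implements in-silico amplicon extraction, uncorrected
    p-distance matrices under pairwise deletion, partitioning of distances
    by taxonomic level, threshold-based species-separation statistics with
    problem-pair detection, and CAOS-style discovery of pure, compound and
    doubly-compound diagnostic nucleotide characters, together with a
    synthetic alignment generator with planted divergences and diagnostics
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
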