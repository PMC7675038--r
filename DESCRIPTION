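Package: deldeck
Title: Design, Simulation, Decoding and Enrichment Analysis for
    DNA-Encoded Chemical Libraries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for single-stranded DNA-encoded chemical library (DEL)
    screening campaigns built on a two-code (CodeA/CodeB) barcode scheme.
    Covers combinatorial enumeration of a split-and-pool library design with
    stereoisomer handling, generation and validation of error-correcting
    barcode codebooks, simulation of affinity-capture selections and
    high-throughput sequencing with known ground truth, error-tolerant
    barcode decoding into CodeA-by-CodeB count fingerprints, enrichment
    factor statistics with hit calling and replicate concordance, and
    single- versus dual-pharmacophore synergy analysis for affinity
    maturation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ggplot2,
    graphics,
    grDevices,
    jsonlite,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
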