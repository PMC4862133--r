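Package: tecensus
Title: Transposable Element Census with Coverage-Based Abundance Correction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Summarizes transposable element (TE) annotations from
    RepeatMasker output by Wicker order and superfamily, computes TE
    densities in fixed-width windows along chromosome-ordered scaffolds
    with region-wise statistical comparisons, corrects assembly-based TE
    abundance estimates using aligned-read depth over annotated positions
    (corrected mass = read base pairs over TE positions divided by a
    reference mean coverage), and compares TE fractions across genome
    assemblies grouped by sequencing technology. Includes a synthetic-data
    generator that emulates assembly collapse of near-identical repeat
    copies, with read alignments whose depth encodes the collapse, so the
    full pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicAlignments,
    IRanges,
    Rsamtools,
    S4Vectors,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    ggplot2,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
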