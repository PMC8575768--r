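Package: snoLatex
Title: snoRNA Discovery and Latex-Regeneration Analysis for the Rubber Tree
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identification of C/D and H/ACA box small nucleolar RNAs (snoRNAs)
    from assembled transcript repertoires, transfer of known rRNA
    2'-O-methylation and pseudouridylation sites from model-organism rRNAs,
    antisense guide-target duplex prediction with GU wobble, blacklist and
    redundancy filtering, pre-rRNA-referenced differential expression between
    leaf and latex, and Spearman correlation of snoRNA expression with latex
    yield potential (TSC/C) and regeneration ability. Ships a synthetic-data
    generator with planted ground truth so the whole pipeline is testable
    without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer,
    limma
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
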