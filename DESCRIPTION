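Package: curdseq
Title: Reference-Free RNA-Seq Differential Expression for Cauliflower Curds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reference-free comparative transcriptomics pipeline for
    organisms without a sequenced genome, built around the analysis of
    green versus white cauliflower (Brassica oleracea) curd tissue.
    Implements hybrid unigene assembly (Sanger EST overlap-layout assembly,
    read alignment with bounded mismatches, de Bruijn assembly of unaligned
    reads, and meta-assembly), read quality control with adaptor and rRNA
    screening, RPKM quantification, differential-expression calling with the
    log-likelihood-ratio R statistic for digital expression data under a
    Poisson model with Benjamini-Hochberg false discovery rate control and a
    fold-change filter, regulator target-set (HY5) overlap accounting,
    functional-category tallies, and spectrophotometric chlorophyll
    quantification via MacKinney coefficients. Includes a fully seeded
    synthetic-data generator with per-read ground truth so every stage can
    be validated against known answers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    data.table,
    tibble,
    dplyr,
    rlang,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
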