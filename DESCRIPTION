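Package: splicecons
Title: Splice-Site Conservation Analysis from Reference-Anchored Genome Alignments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing the evolutionary support of annotated splice
    sites using a reference-anchored multiple genome alignment. Reads MultiZ-style
    MAF alignments into a per-position alignment function, recovers missing
    exon alignments by synteny-guided edit-distance placement with a mean-minus-sd
    score filter, computes per-position conservation feature vectors around donor
    and acceptor sites, classifies sites as well- or less-supported with logistic
    models, and aggregates labels to transcripts, intron categories, population
    SNP-rate profiles, clinical-variant overlap, and junction read-coverage
    summaries. Includes a deterministic synthetic-data generator producing a
    complete test world (genomes, alignment, catalogs, variants, coverage) with
    machine-readable ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    rtracklayer,
    vcfR,
    pROC,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
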