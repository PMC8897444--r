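Package: recodeseek
Title: Detection and Analysis of A-to-I RNA Recoding Sites from RNA-Seq Mismatch Evidence
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects adenosine-to-inosine (A-to-I) RNA editing sites within
    protein-coding sequence from aligned-read mismatch evidence, using a
    three-hypothesis binomial model (sequencing error, rare heterozygous SNP,
    rare homozygous SNP) combined across donors with Fisher's method, together
    with annotation masks, a seed-and-extend self-homology blacklist, mixed-type
    mismatch cluster filtering, strand-consistency and whole-exome filters, and
    editing-level thresholds. Downstream statistics include the pooled RNA
    editing index, cross-species conservation calling with emergence placement
    on a species tree, synonymous/nonsynonymous recoding incidence with
    context-matched randomization, ADAR isoform specificity and influence,
    a variance decomposition separating biological variability of editing
    levels from binomial sampling noise, differential-editing tests (paired,
    group-wise and single-cell), and construction of edited-peptide databases
    for proteomic support. A fully specified cohort simulator with planted
    editing sites, SNPs, paralog misalignment artifacts, antisense transcription
    and sequencing error makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    data.table,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    ape
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    jsonlite,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
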