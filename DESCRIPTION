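Package: chimeraScreen
Title: Screening and Junction-Read Validation of Chimeric RNAs in
    Case/Control RNA-Seq Cohorts
Version: 0.1.0
Authors@R: person("Placenta", "Chimera Lab", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for the downstream screening of chimeric RNA (gene fusion)
    candidates called from RNA-seq data: filtering against a normal-tissue
    background panel, classification of calls by parental-gene location
    (inter-chromosomal, intra-chromosomal, read-through) and by junction-site
    position relative to exon edges (E/E, E/M, M/E, M/M), construction of
    fixed-length junction probes, approximate string matching of probes
    against raw reads with a bit-parallel (bitap) matcher, and case/control
    cohort comparison including group-exclusive chimera sets, cross-cohort
    frequency comparison, marker sensitivity/specificity and parental-gene
    chromosome enrichment. A synthetic-data module generates a complete toy
    universe (genome, annotation, planted chimeras, error-bearing reads and a
    truth ledger) so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    Rcpp,
    stats,
    utils,
    tools,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
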