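Package: spliceswitch
Title: Isoform Switch Discovery in Patient-Matched Tumor Biopsy Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for transcriptome-wide discovery of alternative-splicing
    isoform switches from isoform-level abundance matrices over
    patient-matched baseline and disease-progression biopsies.  Implements
    per-pair differential isoform calling with recurrence ranking and
    concordance filtering, classification of canonical splicing events
    (skipped exon, alternative 5'/3' splice sites, retained intron,
    mutually exclusive exons) from transcript structures, abundance-based
    percent-spliced-in (PSI) testing, reciprocal within-gene switch
    detection, protein domain-impact annotation of alternative isoforms,
    hypergeometric over-representation analysis, and an RNA-binding-protein
    regulator screen.  A ground-truthed synthetic cohort generator emulates
    the matched-pair study design so every stage is testable without
    external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    methods,
    Biostrings,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors,
    yaml,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
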