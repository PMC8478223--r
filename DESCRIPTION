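Package: splicetope
Title: Tumor-Specific Splicing Alterations and Splicing-Derived Neoepitopes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects tumor-specific splicing alterations from per-sample
    splice-junction evidence (aberrant splice sites, neoskipping, de novo
    exonization and intron retention), reconstructs the altered open reading
    frame of each event on the gene's reference transcript with start-codon
    rescue and a 50-nt nonsense-mediated-decay rule, and classifies
    splicing-derived neoepitopes and splicing-affected self-epitopes against
    a pluggable MHC binding-affinity backend. Includes an empirical
    read-support significance test, a randomized mass-spectrometry validation
    test, responder-group affinity comparisons, biomarker enrichment, and a
    seeded synthetic-cohort generator with planted ground truth for
    end-to-end testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
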