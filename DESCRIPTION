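Package: mseekr
Title: Mitochondrial DNA Heteroplasmy Analysis with Circular-Aware Variant
    Calling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying mitochondrial DNA (mtDNA) heteroplasmy in
    matched normal/tumor tissue pairs sequenced by circular-enrichment
    ("Mseek"-style) protocols. Provides a circular mitochondrial reference
    model with gene map and vertebrate mitochondrial genetic code, consequence
    and mutation-spectrum annotation, a read simulator with truth tables
    (phred-scored base errors, clonal duplicates, NUMT-bearing and
    repeat-element nuclear decoys under an exonuclease V digestion model), a
    pileup-based variant caller with non-clonal support, coverage,
    strand-skew and blacklist filters, somatic versus germline classification
    against haplogroup variant-frequency tables, cohort-level
    mutation-spectrum and pooled-heteroplasmy summaries, and Southern-blot
    lane densitometry (band integration, copy-number ratios, catenane
    fractions).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    S4Vectors,
    pracma,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    VariantAnnotation,
    SummarizedExperiment
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
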