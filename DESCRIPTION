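Package: scnatlas
Title: Classification and Pan-Cancer Summarisation of Somatic Copy Number Alterations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies segmented tumor copy-number profiles (SEG files of log2
    copy ratios) into amplified and deleted indels, focal/segmental alterations
    (SCNAs) and chromosome-arm aneuploidies, and summarises them across a tumor
    cohort: per-sample alteration counts and percent genome altered, SCNA length
    statistics, per-chromosome alteration distributions, cancer-gene
    amplification/deletion frequencies via a reciprocal-overlap rule, and
    gene-pair co-amplification/co-deletion matrices. Includes a seeded synthetic
    cohort generator with planted ground truth for end-to-end validation, and a
    multi-stage pipeline driver with deterministic tabular outputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    methods,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
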