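Package: tadmil
Title: Pathogenic Non-Coding Structural Variants from TAD Disruption and
    Multiple-Instance Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies genes putatively disrupted by somatic non-coding
    structural variants (deletions, duplications, inversions,
    translocations) that break topologically associating domain (TAD)
    boundaries or intra-TAD CTCF loops, and classifies the resulting
    SV-gene pairs as pathogenic with a MILES-style multiple-instance
    learner. SV-gene pairs are bags whose instances are the regulatory
    elements (eQTLs, enhancers, super enhancers) the gene gains or loses
    in the derivative domain; instances carry chromatin-annotation
    feature vectors; bags are labelled from patient-matched expression
    z-scores and classified per SV type with a random forest in a
    bag-to-instance distance embedding, evaluated by leave-one-patient-out
    cross-validation. Includes downstream permutation statistics
    (driver potential, instance enrichment, regulatory-track swaps) and a
    synthetic cohort generator with planted pathogenic structure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    IRanges,
    purrr,
    ranger,
    readr,
    rlang,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR
Suggests:
    jsonlite,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
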