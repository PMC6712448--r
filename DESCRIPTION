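Package: poleclass
Title: Classification and Mutational Analysis of POLE-Driven Ultramutated
    Colorectal Tumors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Somatic-variant analysis pipeline for colorectal cancer cohorts:
    false-positive filtering of variant calls by per-variant quality metrics,
    classification of tumors into nonhypermutators, common-hypermutators and
    POLE category (ultramutated) tumors from the nonsynonymous SNV count and
    the six-class substitution spectrum, annotation of POLE protein changes
    for exonuclease-domain membership and pathogenic hotspots, refitting of
    96-context mutational-signature exposures by constrained decomposition
    with forward signature selection, exact and rank-based cohort statistics
    (two-sided Fisher and Mann-Whitney tests, 75th-percentile expression
    normalization), and a synthetic-cohort generator reproducing the
    statistical structure of such cohorts for end-to-end testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    pracma,
    vcfR,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
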