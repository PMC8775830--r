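Package: founderscan
Title: Founder Mutation Detection and Mutation-Burden Analysis for Tumor Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analyzes somatic mutation tables from tumor cohorts to find
    DNA-repair gene "founder" mutations that precede a boost in mutation
    load. Computes per-sample tumor mutation burden from quality-filtered
    mutation calls, tests per-gene and per-pathway association of repair
    mutation status with burden (Mann-Whitney U), quantifies pairwise
    co-mutation enrichment between repair pathways, builds per-sample
    variant-allele-frequency histograms, classifies clonal-expansion
    patterns (single, double/multiple, exponential, neutral), and calls
    founder mutations by a 30-percent frequency-window rule. A synthetic
    cohort generator with full ground truth makes every stage testable, and
    a thin survival stage relates repair-gene expression to relapse-free
    survival via median-split Cox regression and Kaplan-Meier curves.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    survival
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    jsonlite,
    optparse
Config/testthat/edition: 3
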