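Package: bottomline
Title: Consensus GWAS Association Estimates Across Overlapping Published Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for producing a single consensus ("bottom-line") association
    estimate per variant from multiple published genome-wide association study
    (GWAS) summary-statistics datasets. Implements sample-overlap-aware
    fixed-effects meta-analysis with the inter-study correlation of association
    z-statistics estimated from shared null variants, PLINK-style greedy LD
    clumping with an adaptive lead-SNP threshold, cross-approach and
    trans-ancestry signal merging, leave-one-out replication validation of
    consensus-estimation approaches, and post-GWAS concordance machinery
    (shared association regions, credible-set matching by shared posterior
    inclusion probability, through-origin bias regression, and a permutation
    enrichment-walk score). A synthetic multi-cohort generator with known LD
    structure, causal effects, and pairwise sample overlap makes every
    component testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
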