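Package: vigsdesign
Title: Design of Specific Virus-Induced Gene Silencing Fragments for
    Highly Homologous Gene Families
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for selecting short virus-induced gene silencing (VIGS)
    trigger fragments that knock down intended members of a highly homologous
    gene family while avoiding off-target silencing. Implements a sliding
    21-bp window mismatch rule (every window must carry at least three
    mismatches to every off-target transcript, on both strands), a secondary
    filter based on plant miRNA target-recognition rules (5' mismatch budget,
    strict cleavage-site pairing, bounded 3' mismatch loops), a mask-based
    fragment search with efficacy checks against intended co-targets,
    identity-based subgroup clustering with representative selection,
    chimeric multi-fragment construct assembly with junction re-screening and
    overlap-extension PCR primer design, and a deterministic synthetic
    gene-family generator with plantable ground-truth regions for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
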