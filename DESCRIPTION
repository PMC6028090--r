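Package: mugwas
Title: U-Statistics for Genetically Structured Multivariate GWAS
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Case/control genome-wide association testing with u-statistics
    for genetically structured multivariate data (muGWAS). Single SNPs are
    treated as merely monotonic in minor-allele count; neighboring SNPs in a
    linkage-disequilibrium block are combined over sliding windows
    ("diplotypes") with a logical-AND ordering operator, scored by a linear
    score test on subject u-scores, regularized across polarity choices by an
    information-content dominance criterion, and thresholded at an adaptive
    genome-wide significance (aGWS) cutoff estimated from per-chromosome
    quantile-rank curves. Includes a synthetic cohort generator with LD-block
    haplotype pools and implanted monotonic and cis-epistatic risk loci, plus
    type-I error and power harnesses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    vcfR,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
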