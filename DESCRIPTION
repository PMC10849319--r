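Package: xaroh
Title: Coalescent Models of X-Chromosomal and Autosomal ROH and IBD Sharing
    under First-Cousin Consanguinity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Closed-form coalescent predictions for the expected fraction of
    the genome contained in runs of homozygosity (ROH) and in identity-by-
    descent (IBD) segments, on the autosomes and on the X chromosome, in a
    diploid population of N monogamous mating pairs in which a fraction of
    pairs are first cousins of the four classical types (patrilateral/
    matrilateral, parallel/cross). Provides limiting coalescence-time
    distributions with their instantaneous (point-mass) components, expected
    sharing fractions above a minimum segment length, X:autosome sharing
    ratios with their large-N limits, a backward-in-time diploid pedigree
    Monte Carlo that serves as a brute-force check on the analytic results,
    segment-table summaries (genome-length normalized ROH/IBD proportions
    with haplotype-pair weighting and through-origin regressions), and a
    seeded synthetic cohort generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
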