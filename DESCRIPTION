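Package: sweepscan
Title: Selection Scans from Population Branch Statistics and Integrated
    Haplotype Scores with a Coalescent Demographic Null
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects candidate targets of recent positive selection in a
    focal population from phased diploid genotypes.  Computes per-site
    Weir and Cockerham (1984) fixation-index variance components, the
    population branch statistic (PBS) for a focal/ingroup/outgroup trio,
    and the integrated haplotype score (iHS) from extended haplotype
    homozygosity (EHH) decay.  Empirical PBS p-values are drawn from a
    built-in coalescent simulator of a three-population divergence and
    bottleneck model; candidate variants are taken as the intersection of
    the top tails of both statistics, then summarised by per-gene and
    per-regulatory-element selection density, genic consequence category,
    and local-ancestry context.  A forward Wright-Fisher simulator with
    selection, recombination and population splits generates fully
    synthetic phased test data with implanted sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vcfR,
    GenomicRanges,
    IRanges,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    Biostrings,
    rtracklayer,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
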