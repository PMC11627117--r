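Package: inbredscope
Title: Runs of Homozygosity, Haplotype Dating and Genetic Load in Small Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterising recent inbreeding and deleterious
    variation in small multi-species genotype cohorts. Implements strict
    site- and genotype-level VCF filtering, a model-based windowed
    genotype-LOD caller for runs of homozygosity (ROH) with kernel-density
    threshold selection and fixed size classes, dating of the haplotypes
    underlying ROH via the exponential length-age relationship
    (l = 100/(2g) cM) with chromosome-size-binned recombination rates,
    the inbreeding coefficient F_ROH, masked and realized deleterious-load
    accounting from transcript-level consequence annotations with exact
    Mann-Whitney U comparisons, private-allele unfolded site frequency
    spectra by hypergeometric projection, and relatedness and structure
    checks (allele-sharing distance with classical MDS, KING-robust
    kinship, Weir-Cockerham Fst). A synthetic-data generator plants
    autozygous tracts of known age so every stage is verifiable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    vcfR,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
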