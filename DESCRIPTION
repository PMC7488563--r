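Package: sweepscan
Title: Selective-Sweep Scans, DCMS Composite Scores, and Runs of
    Homozygosity for Multi-Population Genotype Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Windowed selection scans on diploid genotype data from
    several populations: within-population statistics (SweepFinder-style
    composite likelihood ratio against the background site-frequency
    spectrum, integrated haplotype score iHS) and cross-population
    statistics (heterozygosity-partition F_ST, XP-EHH), averaged in 50-kb
    windows and combined into de-correlated composite of multiple signals
    (DCMS) scores with skew-normal empirical p-values and top-quantile
    sweep-region calling.  Also provides PLINK-style detection of runs of
    homozygosity with F_ROH inbreeding coefficients and population ROH
    hotspots, genotype PCA and permutation-tested AMOVA, hard-filtering of
    variant calls, interval annotation against feature tables, and a
    synthetic multi-population genotype simulator with injected sweeps and
    autozygous tracts that supplies ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    vcfR,
    GenomicRanges,
    IRanges,
    S4Vectors,
    multcomp,
    rlang
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan,
    jsonlite,
    optparse
Config/testthat/edition: 3
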