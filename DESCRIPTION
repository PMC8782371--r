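Package: ohia
Title: Population Genomics of an Incipient Three-Cluster Woody Radiation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Windowed diversity and differentiation statistics, a
    four-method selective-sweep scan with an integration layer, and
    three-dimensional site-frequency-spectrum demographic model comparison
    for a three-cluster plant radiation, exercised end-to-end on synthetic
    structured-coalescent data. Includes a structured-coalescent simulator
    with population splits, epoch-dependent migration and optional hard
    sweeps; nucleotide diversity, Watterson's theta, Tajima's D, Dxy,
    Weir-Cockerham FST, runs of homozygosity and LD decay with
    missing-data-aware denominators; cross-population extended haplotype
    homozygosity, a composite sweep statistic, kNN FST-vector outlier
    detection and Fisher-exact signal integration; PCA, distance-based
    Moran's eigenvector maps, redundancy analysis with forward selection
    and variance partitioning; and composite-likelihood fitting of a
    24-model divergence/migration family with AIC comparison and
    parametric bootstrap.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    vcfR,
    IRanges,
    GenomicRanges,
    S4Vectors,
    Biostrings,
    rtracklayer,
    geosphere,
    vegan,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
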