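Package: hyperphen
Title: Whole-Plant Hyperspectral Phenotyping and Downstream Genetic Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pipeline for high-throughput hyperspectral plant phenotyping and
    its downstream genetics. Ingests raw band-interleaved hyperspectral
    streams, calibrates them to reflectance with dark and white reference
    frames, segments the plant from the background, and extracts a 1,540-index
    feature catalog per plant (per-band total and average reflectance, their
    first and second wavelength derivatives, and characteristic red-edge /
    green-peak / red-valley indices) plus the projected area. Downstream it
    fits stepwise linear regression models for agronomic traits with k-fold
    cross-validation, screens index-trait correlations, classifies growth
    stages by stepwise discriminant analysis, estimates heritability and
    genetic correlation by bivariate REML on a genomic relationship matrix,
    selects heritable hyper-traits, and post-processes genome-wide
    association results into lead SNPs (LD clumping), merged loci, candidate
    gene windows, and haplotype contrasts. A synthetic-data generator
    produces every input with stored ground truth so the whole pipeline is
    testable without field data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    MASS,
    EBImage,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    rtracklayer,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
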