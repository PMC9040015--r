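Package: gwaskit
Title: Memory-Efficient Genome-Wide Association Scans with GLM, MLM and
    FarmCPU
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A complete genome-wide association study (GWAS) engine built
    around a file-backed genotype store. Converts VCF, PLINK binary,
    HapMap and numeric dosage inputs into an on-disk marker-by-sample
    matrix that is streamed block-by-block, builds the VanRaden genomic
    relationship matrix and principal components from a single
    eigendecomposition that is reused across the whole pipeline,
    estimates variance components by Brent REML, EMMAX-style grid
    search, a low-rank spectral route and Haseman-Elston regression,
    and runs per-marker association scans (general linear model, mixed
    linear model under P3D, and iterative FarmCPU) accelerated by a
    blockwise design-matrix inversion so the covariate block is
    inverted once per scan. Includes publication-quality Manhattan,
    quantile-quantile, marker-density, phenotype-distribution and PCA
    plots, and a genotype/phenotype simulator with known truth for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    parallel,
    tools,
    jsonlite,
    data.table,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
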