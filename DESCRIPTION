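Package: nutriGWAS
Title: Mixed-Model GWAS of Root Growth Under Single and Combined Nutrient
    Deficiencies
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end association-mapping pipeline for root growth
    rate (RGR) phenotypes of inbred Arabidopsis thaliana accessions grown
    under control and nutrient-deficient media (-P, -Fe, -Zn and their
    combinations). Estimates per-accession growth rates by pooled linear
    regression of primary root length on seedling age, builds normalized
    (deficiency/control) and delta (combined minus single deficiency)
    traits, performs kinship-corrected mixed-model association scans with
    REML variance components (EMMAX-style single fit), reports
    pseudo-heritability, maps significant markers to candidate genes via
    fixed-width windows against a gene annotation, tests cross-trait SNP
    overlap with hypergeometric and resampling nulls, and mines connected
    candidate-gene modules in a weighted co-function network with
    annotation-term enrichment. Includes a synthetic-data generator with
    planted genetic architecture (Balding-Nichols population structure,
    condition-specific and interaction QTLs, polygenic background) for
    validation and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    rtracklayer,
    igraph,
    vcfR,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'io.R'
    'mapping.R'
    'mixedmodel.R'
    'network.R'
    'nutriGWAS-package.R'
    'overlap.R'
    'phenotypes.R'
    'pipeline.R'
    'plots.R'
    'simulate.R'
    'utils.R'
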