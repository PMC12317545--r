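Package: phosGWAS
Title: Phosphorus-Efficiency Phenomics and Marker-Trait Association for
    Diversity Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for screening crop diversity panels for phosphorus (P)
    efficiency under contrasting fertilization (high-P control vs. low-P
    stress) and for mapping the trait variation to markers. The package
    derives P-uptake and P-utilization traits from raw measurements,
    partitions phenotypic variance by two-way ANOVA into genotype,
    treatment and interaction components with broad-sense heritability,
    scores genotypes by the stress tolerance index (STI) and its
    membership-function composite (MFVP), clusters performance profiles
    on z-standardized trait matrices, and runs a principal-component
    adjusted single-marker association scan over quality-controlled SNP
    dosages with Bonferroni control, per-SNP phenotypic variance
    explained, and candidate-gene window queries against GFF3
    annotation. A synthetic-panel generator with planted marker effects
    makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    S4Vectors,
    SummarizedExperiment,
    GenomicRanges,
    IRanges,
    rtracklayer,
    vcfR
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'phosGWAS-package.R'
    'AllGenerics.R'
    'AllClasses.R'
    'io-phenotypes.R'
    'io-genotypes.R'
    'io-annotation.R'
    'simulate.R'
    'phenostats.R'
    'tolerance.R'
    'cluster.R'
    'association.R'
    'pipeline.R'
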