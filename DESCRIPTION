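Package: phenosig
Title: Predictive B-Vitamin Phenotype Profiling of Microbial Communities
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Projects 16S rRNA-derived community profiles onto a reference
    binary phenotype matrix of B-vitamin biosynthesis phenotypes to estimate
    community-wide prototrophy and auxotrophy. Phylotypes are mapped to a
    curated genome collection at species, genus or family rank by sequence
    identity; phenotype indices are obtained by hierarchical equal-weight
    averaging of binary genome phenotypes; per-sample Community Phenotype
    Indices and auxotrophy signatures are computed as abundance-weighted
    totals, optionally after 16S rRNA gene copy-number renormalization.
    Includes taxon classification (mono-/multi-auxotroph, omni-prototroph),
    replicate-group aggregation, nonparametric diet-group comparison, and a
    synthetic-study generator with Dirichlet-multinomial noise for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    biomformat,
    optparse,
    knitr
Config/testthat/edition: 3
biocViews: Microbiome, Metagenomics, Software
RoxygenNote: 7.3.3
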