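Package: gutBrainRank
Title: Rank-Product Association of Gut Microbiome OTUs with Brain
    Diffusion-Tensor Measurements
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Links gut-microbiome OTU relative abundances to diffusion-tensor
    imaging measurements of brain white matter through diet, using random
    forests with out-of-bag permutation importance. Provides diet
    classification with leave-one-out and repeated stratified nested
    cross-validation, per-region random-forest regression of z-scaled
    diffusion metrics on OTU abundances, and a rank-product scoring scheme
    that combines three importance rankings into a single score used to
    prioritise OTU to brain-region pairs. Includes a synthetic-cohort
    generator with planted diet effects and OTU-linked brain effects so the
    whole pipeline can be exercised and calibrated without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    randomForest,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    pheatmap,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Microbiome, Classification, Regression, Metagenomics
Collate: 
    'AllClasses.R'
    'accessors.R'
    'forest_engine.R'
    'diet_predict.R'
    'gutBrainRank-package.R'
    'pair_score.R'
    'preprocess.R'
    'report.R'
    'synthetic_cohort.R'
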