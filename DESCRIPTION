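Package: tumortracer
Title: Tumor Type Classification from Somatic Passenger and Driver Mutation Patterns
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts regional mutation density (RMD) profiles over megabase
    genomic windows, 96-channel trinucleotide mutation spectra (MS96) and
    binary driver-mutation features (genes, pathways, hotspots) from somatic
    mutation catalogs, trains one-vs-rest support vector machine and random
    forest classifiers for tumor type / tissue-of-origin prediction, and
    evaluates them with repeated stratified cross-validation (ROC/AUC,
    precision-recall/AUPRC, recall at fixed precision, complementarity
    analysis, feature importance consensus). Includes a synthetic tumor
    cohort generator with class-specific window intensities, spectrum
    mixtures, driver-gene hit probabilities and log-normal mutation burden,
    and perturbation tools emulating exome capture and false-negative
    mutation calls.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    e1071,
    randomForest,
    glmnet,
    cluster,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    vcfR,
    rtracklayer
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
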