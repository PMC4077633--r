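Package: gpnorm
Title: Gaussian-Process Normative Modeling of Volumetric Brain Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Individualized normative modeling of voxel-based morphometry
    data with exact Gaussian-process regression. Trains one GP per masked
    voxel (squared-exponential ARD kernel, marginal-likelihood
    hyperparameter optimization, optional voxelwise Box-Cox
    transformation) on healthy-control covariates, and scores new
    subjects with Normative Probability Maps (voxelwise z-scores of the
    predictive distribution) and global tissue-volume z-scores. Includes
    a two-level mixed-effects lifespan trajectory simulator for
    validation, single-case t-test and GLM prediction baselines, ROC/AUC
    evaluation, and a command-line interface over NIfTI volumes and CSV
    covariate tables.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    RNifti,
    stats,
    utils,
    yaml
Suggests:
    MASS,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
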