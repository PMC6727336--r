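Package: breastdti
Title: Diffusion Tensor Imaging Features for Breast Lesion Diagnosis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for quantifying the added diagnostic value of diffusion
    tensor imaging (DTI) over clinical and dynamic contrast-enhanced (DCE)
    MRI features of suspicious breast lesions: diffusion tensor estimation
    from multi-direction diffusion-weighted MRI with scalar parametric maps
    (apparent diffusion coefficient, fractional anisotropy, axial and radial
    diffusivity), semi-automated lesion region-of-interest refinement on the
    combined diffusion-weighted image, enhancement-curve kinetic
    classification, cluster-robust univariate logistic modeling, LASSO
    multivariate models with leave-one-patient-out penalty selection, and
    bootstrap optimism-corrected AUC internal validation with patient-level
    resampling. Includes a synthetic-data generator producing diffusion
    phantoms with known tensors, enhancement curves with known kinetic
    class, and clustered lesion cohorts with known effect structure.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    glmnet,
    jsonlite,
    RNifti,
    sandwich,
    stats,
    utils,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
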