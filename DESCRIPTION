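Package: rtforecast
Title: Image-Informed Forecasting of Tumor and Vasculature Response to
    Fractionated Radiotherapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Calibrates and forecasts a family of mechanically coupled
    reaction-diffusion models of tumor and vasculature growth under
    fractionated radiotherapy, driven by voxelwise tumor and blood
    volume-fraction maps derived from quantitative MRI. Provides the
    coupled cross-diffusion PDE system with a stress-damped diffusion
    coefficient, three radiotherapy response models crossed with three
    spatial-efficacy couplings and global or voxelwise proliferation
    fields (an 18-member family), hybrid simulated-annealing plus
    Levenberg-Marquardt calibration with Wald confidence intervals,
    corrected-AIC model selection and Akaike-weighted ensemble
    forecasts, global and local agreement metrics, measurement models
    for inversion-recovery T1, ADC-based cellularity and DCE blood
    volume mapping, and a synthetic virtual-animal generator with
    ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    EBImage,
    jsonlite,
    Matrix,
    methods,
    minpack.lm,
    Rcpp,
    RNifti,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
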