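Package: nafads
Title: Surface-Adsorption Simulation and Quantification of 18F-Sodium-Fluoride
    Binding to Vascular Calcification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates and quantifies the adsorption of the PET tracer
    18F-sodium-fluoride to the accessible surface of vascular calcification.
    Provides digital carotid-plaque phantoms with micro- and macrocalcific
    deposits, a one-site surface-binding kinetic model producing ground-truth
    activity maps, multi-resolution imaging simulation (autoradiography,
    micro-PET/CT and clinical PET/CT point-spread functions with noise),
    the associated image-quantification pipeline (Otsu and Li automatic
    thresholding, mask refinement, Pearson co-localization, PET/CT tri-class
    accounting, linear transect profiles), and kinetic analyses: association
    and dissociation fits with derived affinity constants, log-log
    concentration-response calibration, biexponential plasma models, dynamic
    study synthesis and Patlak graphical analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    Rcpp,
    readr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    tiff,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    EBImage,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
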