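Package: renalseg
Title: Dual-Phase CT Segmentation and Surface Modelling for Renal Stone
    Surgery Planning
Version: 0.1.0
Authors@R: person("renalseg", "developers", role = c("aut", "cre"),
    email = "renalseg@example.org")
Description: Headless pipeline for percutaneous nephrolithotomy (PCNL)
    planning from dual-phase abdominal CT. Reads a non-contrast (native)
    and a delayed excretory-phase volume (DICOM series or MetaImage),
    applies a linear intensity band shift, median denoising and rigid
    mutual-information co-registration, then segments skeleton, contrast
    filled pelvicalyceal system and renal calculi by fixed-band histogram
    thresholding with morphological particle removal. Reports stone volume
    (SV), pelvicalyceal system volume (PSV) and the SV/PSV burden ratio,
    and exports watertight triangulated surfaces as STL. Ships a synthetic
    dual-phase phantom generator with analytic ground truth so the whole
    chain is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
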