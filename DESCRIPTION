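Package: dwiQA
Title: Quality Assurance of Apparent Diffusion Coefficient Measurements on
    Diffusion Phantoms and Multi-Scanner Studies
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantitative quality assurance of diffusion-weighted
    MRI derived apparent diffusion coefficient (ADC) measurements. Provides a
    packaged description of the 13-vial isotropic (PVP) diffusion phantom with
    NIST-characterized reference diffusivities, a synthetic generator for
    phantom and simple in vivo diffusion series (mono-exponential decay,
    Rician noise at a calibrated SNR, per-scanner bias and session drift),
    pixel-wise log-linear and two-point ADC map fitting with rescale handling,
    automated circular vial regions of interest and organ-mask statistics, the
    QIBA Diffusion Profile conformance test battery (bias, short-term and
    between-session repeatability, linearity, precision, SNR and b-value
    dependence with the published tolerances), and multi-scanner aggregation
    of per-vial bias and reproducibility. Readers and writers for a NIfTI plus
    b-value sidecar dialect and a minimal single-frame DICOM dialect are
    included, along with tidy CSV reports.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    RNifti,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'dwiQA-package.R'
    'AllClasses.R'
    'config-io.R'
    'phantom-layout.R'
    'simulate.R'
    'adc-fit.R'
    'roi.R'
    'conformance.R'
    'study-summary.R'
    'io-nifti.R'
    'io-dicom.R'
    'pipeline.R'
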