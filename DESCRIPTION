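Package: nemaiq
Title: NEMA IQ Phantom Simulation and Gallium-68 PET Harmonisation Metrics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates PET acquisitions of the NEMA IEC body phantom with
    controllable resolution, Gibbs-type edge enhancement and spatially
    correlated noise, and implements the image-quality analysis used to
    standardise Gallium-68 multi-centre PET-CT studies: 50%-isocontour sphere
    segmentation, the 360-region background battery, recovery and contrast
    recovery coefficients, background variability and image roughness,
    peak-to-valley edge-artifact profiling, derivation of multi-scanner
    specification limits (mean plus or minus 2 SD) with compliance checking,
    and Bland-Altman agreement of lesion uptake values between reconstruction
    variants.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    RNifti,
    yaml,
    jsonlite
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
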