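Package: dectpellet
Title: Shotgun Pellet Material Differentiation with Dual-Energy CT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fully automated analysis of dual-energy computed tomography
    (DECT) scans containing metallic shotgun pellets. Computes dual-energy
    index (DEI) volumes from co-registered low/high-kVp acquisitions on the
    extended Hounsfield scale, segments pellets by fixed-threshold masking,
    in-plane disk erosion and 3D connected-component labelling, summarizes
    per-pellet DEI, and discriminates pellet materials (steel, copper versus
    lead, tungsten, bismuth) with pairwise two-sided Wilcoxon rank-sum tests.
    Includes mass-attenuation physics for theoretical DEI prediction and a
    seeded synthetic gelatine-block phantom generator with ground-truth
    sidecars for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
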