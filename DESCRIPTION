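Package: ipchemo
Title: Drug Transport and Penetration in Peritoneal Tumor Nodules During
    Intraperitoneal Chemotherapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computational model of drug transport in a single vascularized
    peritoneal tumor nodule bathed in cytotoxic solution during
    intraperitoneal (IP) chemotherapy.  Solves the steady interstitial fluid
    pressure problem (Darcy flow in a rigid porous interstitium with a
    Starling transvascular filtration source and no functional lymphatics)
    and, on the frozen velocity field, the transient convection-diffusion-
    reaction equation for interstitial drug concentration with first-order
    cellular elimination and vascular resorption sinks.  Provides six
    parametric nodule geometries (large/small sphere, ellipsoid and cropped
    'peritoneal' shapes, each with a necrotic core), penetration-depth and
    pressure-profile metrics (IFP_max, LP50, APD, PD%, Peclet numbers),
    one-command parameter studies (drug type, vascular normalization,
    necrotic core omission, tissue permeability), and closed-form spherical
    oracles for verification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    stats,
    graphics,
    grDevices,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
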