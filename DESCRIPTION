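Package: fermscale
Title: Stirred-Tank Fermenter Scale-Up, Impeller Selection and
    Gate-to-Gate Life Cycle Impact
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Engineering calculations for scaling up stirred-tank (CSTR)
    fermenters from laboratory and pilot vessels to industrial scale.
    Covers geometric similarity bookkeeping, impeller Reynolds number and
    flow-regime classification, power-number correlations, mixing power
    draw, agitator torque, specific power on working- and total-volume
    bases, the Kolmogorov turbulence microscale as a cell-shear screen,
    constant power-per-volume scale-up rules, impeller staging and count
    bounds, an impeller-type by agitation-speed design matrix with
    selection criteria and motor sizing, and an electricity-only
    gate-to-gate life cycle impact model with geometric scenario sweeps.
    Ships a worked whey-permeate lactic acid fermentation case study
    spanning 0.003, 0.1 and 300 cubic metre vessels, plus a seeded
    generator of physically plausible scenarios for property testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
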