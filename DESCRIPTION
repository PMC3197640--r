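Package: ehtforce
Title: Video-Optical Contractility Analysis for Engineered Heart Tissue
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Analysis pipeline for force traces from fibrin-based engineered
    heart tissue (EHT) suspended between elastic silicone posts. Converts
    post deflection to contractile force by cantilever beam mechanics,
    detects spontaneous contraction twitches and measures their amplitude
    and contraction/relaxation kinetics, quantifies beat-to-beat rhythm
    irregularity (interdecile-range scatter, Poincare pairs, exact
    Mann-Whitney tests), determines threshold concentrations in cumulative
    dose-response experiments, and scores sarcomere alignment from
    orientation-angle samples. A synthetic-data module generates
    ground-truth-annotated twitch traces (and marker-tracking video frames)
    emulating spontaneously beating human EHTs, including calcium,
    beta-adrenergic and proarrhythmic drug effects, so every stage of the
    pipeline can be validated without laboratory recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
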