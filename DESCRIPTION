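Package: rotorbat
Title: Acoustic and 3D Stereo-Thermal Analysis of Bat Activity at Wind Turbines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing bat activity recorded at wind-turbine nacelles.
    Classifies parameterised echolocation call streams into species and species
    groups, detects feeding buzzes and social vocalisations, and assembles song
    events. Models atmospheric sound absorption (ISO 9613-1), recorder detection
    ranges and the active space of bat song. Reconstructs 3D bat positions from
    synchronised stereo thermal-camera detections, estimates bat density in 3 m
    spherical shells around the nacelle with camera-view clipping, and fits an
    exponential-attraction density model. Fits binomial mixed models comparing
    feeding and social activity between acoustic species groups across months.
    Ships seeded synthetic-data generators for call-event streams, 3D flight
    scenes and activity tables so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    emmeans,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
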