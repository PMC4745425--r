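Package: pulsewave
Title: Pulse-Wave Haemodynamics in Arteries with Segment-Wise Compliance Mismatch
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale models of pulsatile blood flow through a straight
    artery whose middle segment is far more compliant than its ends, the
    configuration created by bypass grafting with a stiff conduit. Provides a
    deterministic carotid-like inlet waveform generator, the closed-form
    Womersley solution for pulsatile flow in a rigid tube (velocity profiles,
    wall shear stress, pressure gradient), a second-order one-dimensional
    area-averaged fluid-structure solver with a segment-wise elastic tube law
    (MacCormack scheme, characteristic boundary treatment), thick-walled
    Lame hoop stress and strain post-processing, and tidy per-location
    summaries of wall shear stress, pressure, circumferential stress and
    strain for quantifying the mechanical consequences of compliance
    mismatch at graft junctions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
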