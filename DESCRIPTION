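Package: agilitrack
Title: Automatic Footstep Registration for Reactive-Agility Training
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Registers footstep-in-contact-region events from frontal video
    of a reactive-agility training platform, with no on-body sensors.
    Combines Gaussian-mixture background subtraction, per-foot Kalman
    tracking with a two-threshold step decision, planar homography mapping
    from pixels to metric floor coordinates, and a 30 cm contact-region rule
    to score which target a player reached, when, and whether the response
    was correct. Includes a synthetic session generator with exact ground
    truth and a temporally tolerant event-matching evaluation protocol
    (precision, sensitivity, specificity, F1, per-target timing error).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    Rcpp,
    jsonlite,
    yaml,
    png
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    EBImage
Config/testthat/edition: 3
RoxygenNote: 7.3.3
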