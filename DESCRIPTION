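Package: dresstrack
Title: Rule-Based Dressing-State Detection from Fiducial Marker Streams
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts time-stamped fiducial-marker observation streams from
    camera-tracked garments (shirts and pants) into dressing-state detections
    (front, back, inside-out, limb worn, misaligned, partial, complete) using
    a temporal rule engine with visibility persistence, partial-dressing
    timeouts, and velcro-alignment arithmetic.  Includes a six-phase
    evaluation harness that scores detection sequences against per-condition
    expectation tables, a seeded scenario simulator that generates synthetic
    marker streams for nine dressing conditions with realistic failure modes
    (occlusion, distance-dependent dropout, transient glimpses), and a
    deterministic dressing-session state machine for prompting and caregiver
    escalation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
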