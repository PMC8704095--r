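Package: strikeDetect
Title: Automated Detection of Bird and Bat Collision Fatalities in
    Nacelle Camera Imagery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects bird and bat collision fatalities below wind turbines
    from downward-facing nacelle cameras, using a visible/near-infrared
    channel for daytime and a thermal (LWIR) channel for nighttime. A
    first-in-first-out temporal image stack is registered, brightness
    normalized, and scored pixel-wise (a lookup-shifted step score with
    temporal-variation penalties for the visible channel, a median
    difference of the stack halves for the thermal channel). Candidate
    regions are generated by adaptive thresholding and morphology, filtered
    by preselection criteria (area, temporal and spatial discernibility,
    surround score) and accepted by structural-similarity (SSIM/SDIFF)
    criteria on the stack's consecutive frame pairs. Includes a seeded
    synthetic scene simulator (vegetation texture, illumination steps, wind
    fluctuation, transient animals, persistent cooling drops) and an
    evaluation harness computing sensitivity and false-positive rates
    against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    EBImage,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    yaml,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
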