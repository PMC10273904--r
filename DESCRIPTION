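Package: melodyarc
Title: Melody Arc Decomposition and Complexity Analysis of Infant Vocalizations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools to analyse the fundamental-frequency (f0) contour -- the
    melody -- of infant cry and babbling vocalizations. Reads PRAAT PitchTier
    and CSV f0 tracks, converts f0 to a musical (semitone) scale, smooths
    contours with a Gaussian low-pass filter, decomposes melodies into
    ascending-then-descending arcs under vocalization-type-specific duration
    and frequency-modulation criteria, detects intra-melodic segmentation
    events (laryngeal constrictions), and classifies each vocalization as
    single-arc (SA), double-arc (DA), triple-arc (TA), multiple-arc (MA) or
    segmented (SEG). Includes a seeded synthetic-corpus generator with known
    ground-truth melody structure, developmental profile aggregation by age
    and vocalization type, and mixed-effects logistic models of melody
    complexity with a per-infant random intercept.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
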