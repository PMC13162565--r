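Package: avdeid
Title: De-Identification Pipeline for Clinical Audio-Video Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A six-stage pipeline for removing protected health information
    (PHI) from clinical audio-video recordings. Parses diarized transcripts
    with word-level timestamps, detects and redacts PHI with a rule-based
    lexicon and pattern engine, maps redacted words to millisecond audio
    intervals and replaces them with tones, disguises speaker identity by
    pitch and spectral-envelope transformation, obscures faces in video via
    pose-keypoint tracking (linear gap interpolation plus constant-velocity
    Kalman smoothing) with selective or whole-frame Gaussian blurring,
    re-synchronizes and multiplexes the processed streams, and runs automated
    quality-control checks. Ships a deterministic synthetic fixture generator
    (transcripts with planted PHI, harmonic voice-like audio, stick-figure
    pose clips) and a hash-chained artifact ledger for auditability.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    png,
    IRanges,
    S4Vectors,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
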