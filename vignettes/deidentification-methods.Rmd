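---
title: "Methods: de-identifying clinical audio-video recordings"
author: "avdeid"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: de-identifying clinical audio-video recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(avdeid)
```

# The problem and the model

Audio-video recordings of clinical encounters carry protected health
information (PHI) in three coupled channels: the words spoken, the voices
speaking them, and the people and places visible on camera. `avdeid`
treats the channels separately — text redaction drives audio scrubbing
through word-level timestamps, while video obscuration is driven entirely
by pose keypoints — and recombines them only at the end, under an audit
trail. This vignette explains each model, its assumptions, the tunable
parameters, and what the synthetic tests do and do not establish.

## Transcripts as the timing spine

The transcript data model assumes an upstream ASR/diarization system has
already produced word-level timestamps (WhisperX-style JSON). Timestamps
are stored as **integer milliseconds** (half-up rounding at parse time)
with half-open intervals `[start, end)`; this makes interval arithmetic
exact and serialization byte-stable, at the cost of sub-millisecond
precision nobody downstream needs. Word indices are global and assigned in
document order, so a redaction span is always a word-index range — never a
sub-word character range — and the mapping from placeholders to audio time
is the identity on word indices. Overlapping speech is allowed (segments
of different speakers may overlap); a word missing its confidence score
gets 1.0 with a warning rather than a hard failure, a deliberate tolerance
for non-WhisperX back ends. Confidence scores are carried but gate
nothing: no published evidence says how they should modulate redaction, so
the conservative choice is to redact regardless.

## Rule-based redaction

The rule engine covers six categories: NAME and LOCATION by case-folded
lexicon lookup (single tokens or multi-word phrases), DATE, ID, CONTACT
and AGE by ordered regex patterns applied to punctuation-stripped tokens.
Three design rules make it deterministic:

* the **safe lexicon always wins** — a token or phrase listed there is
  never redacted, whatever else matches;
* overlaps resolve **longest match first**, ties broken by patterns before
  lexicons, then rule order, then position;
* matching is case-insensitive with leading/trailing punctuation stripped
  (internal punctuation is preserved, so `03/14/2019` and `555-0147`
  still match their patterns).

Tokens equal to a rendered placeholder are skipped during detection, which
makes redaction idempotent. The shipped pattern set is deliberately small
— a starting point to be extended per institution, not a full HIPAA Safe
Harbor rule base; the six-category inventory itself is an interpretation
(categories like biometric identifiers have no textual surface here).
Context-aware NER is out of scope by design: a rule engine is auditable,
and auditability is the point in this domain.

## Audio scrubbing

Each PHI span maps to `[min word start, max word end)` over its words.
Intervals closer than `mergeGapMs` (default **50 ms**) are merged so no
audible sliver of speech survives between adjacent PHI words; no other
padding is added, because the timestamps are taken at face value and
over-scrubbing destroys conversational content. Merging uses
`IRanges::reduce()` on the closed integer images of the half-open
intervals; the test suite checks it against an independently written
sort-and-sweep oracle.

Scrubbed intervals are filled with a **tone** rather than silence, since
pauses themselves can convey clinical meaning. Defaults: 440 Hz, amplitude
0.2, 10 ms linear fades — audible, unclipped, and far (in frequency) from
the harmonics of typical speech F0. The tone is phase-continuous in
absolute time (`sin(2π f n / sr)` at absolute sample index `n`), so its
samples are exactly reproducible by construction, which the tests exploit.

**Voice disguise** scales the fundamental frequency by a ratio drawn
log-uniformly from [0.7, 0.85] ∪ [1.2, 1.45] — near-identity values are
excluded so the disguise is never a no-op — and warps the spectral
envelope by a factor in [0.9, 1.1] (the envelope range is a placeholder
judgment call: large warps make speech unintelligible, tiny ones do
nothing). One draw per **speaker label**, so each speaker keeps a single
consistent disguise within a file; a `scope = "file"` switch applies one
draw to the whole track instead, since diarization quality varies. The
reference vocoder is a phase vocoder: time-stretch by the ratio (constant
synthesis hop 256, frame 1024, Hann window, phase propagation by
heterodyned phase increments), then linear-interpolation resampling at
exactly the ratio back to the original sample count. Two consequences are
guaranteed structurally: the sample count never changes (speed is
untouched), and the frequency axis scales by exactly the requested ratio
(the resampling step does the scaling arithmetically; the vocoder only has
to preserve periodicity). Inverting the ratio does not recover the
original waveform — overlap-add and interpolation artifacts accumulate —
which the suite verifies as a relative RMS error above 0.1 on
word-structured audio. That is a weak, testable proxy for
irreversibility, not a cryptographic claim, and no speaker-verification
attack model is evaluated. An alternative vocoder (e.g. a WORLD-style
analysis/synthesis engine) can be supplied as any function with the
`phaseVocoderBackend()` signature.

The F0 oracle used in tests, `estimateF0Track()`, is a frame-wise
normalized-autocorrelation estimator (40 ms frames, 10 ms hop, search
range 60–450 Hz, parabolic peak interpolation, voicing threshold 0.5 on
the ACF peak plus an RMS floor of 1e-4). On pure tones it is accurate to
well under 1 Hz; on white noise it reports under 20% voiced frames.

## Video obscuration

The video stage consumes per-frame 17-keypoint COCO pose detections; pose
estimation itself is upstream. Processing order is association →
interpolation → Kalman smoothing → obscuration, matching the narrative
order in which tracking refinements are usually described.

* **Association** is greedy nearest-centroid with a distance gate
  (`maxMatchDistPx`, default 50 px): deterministic, order-independent at
  the frame level, and adequate when subjects stay farther apart than the
  gate — the documented assumption. Optimal bipartite assignment would
  change results only when two detections contest one track inside the
  gate.
* **Interpolation** fills interior gaps up to `maxGapFrames` (default
  **30**, about one second at 30 fps) on the exact connecting line per
  coordinate; leading/trailing gaps are constant-extended. Longer gaps
  are *not* guessed — they stay `missing` and are flagged to QC. In
  `processVideo()` tracks are extended over the full clip range, which
  conservatively blurs a person from frame 0 even if they were first
  detected later; fabricating presence costs pixels, missing a face costs
  privacy.
* **Kalman smoothing** runs an independent constant-velocity filter per
  coordinate series (34 per person): transition `[[1,1],[0,1]]`,
  white-acceleration process noise `q·[[1/4,1/2],[1/2,1]]` with `q = 1`
  px², measurement variance `r = 4` px², initialized at the first
  measurement with zero velocity and covariance `diag(r, 100)`. The suite
  pins the recursion to a hand-computed scalar implementation at 1e-9 and
  verifies RMSE improvement on noisy constant-velocity simulations.

**PPP (precision mode)** blurs the axis-aligned hull of the confident
facial keypoints (confidence ≥ `kpConfThreshold`, default 0.3), expanded
by `bboxMarginFrac` (default **0.25**) of the hull diagonal on every side.
The margin absorbs detection jitter, interpolation error at trajectory
corners and Kalman lag; 25% of the face diagonal covers all three at the
fixture's noise levels with room to spare. A zero-diagonal hull (all
facial points coincident) gets a floor-size box (`minBoxPx`, default 16
px). A person with *no* confident facial keypoint yields no box at all and
the frame is flagged to QC rather than silently passed — the one
genuinely unsafe case a margin cannot fix. Blur sigma defaults to the box
diagonal / 6 (so the blur scales with apparent face size); each region is
blurred on a kernel-padded crop, which equals full-frame blur on the
region interior while keeping cost proportional to the face, and makes
the locality guarantee — *no pixel outside any box changes, bit-exactly*
— structural rather than numerical.

**GPP (greedy mode)** blurs the entire frame (sigma default: frame
diagonal / 100) and draws the skeleton: discs (radius 3 px) at confident
keypoints and 2 px segments along the standard COCO limb pairs. The
overlay style is fully configurable; the COCO convention is used because
no rendering standard exists for this purpose.

## Synchronization and muxing

Offsets come from the ledger of stage-logged delays (`audio − video`),
not from signal cross-correlation: every operation in this pipeline
conserves durations exactly, so the delays are known to be zero and the
mechanism exists for externally induced delays. A positive offset trims
the audio start, a negative one pads it with silence; durations are then
equalized to the video (policy `pad` extends the shorter stream — silence
or frozen frames — `trim` cuts the longer). The built-in muxer writes
uncompressed 24-bit DIB video plus 16-bit PCM audio into a RIFF/AVI
container in pure R: a lossless profile with no embedded timestamps, so
outputs are bit-stable, probes are exact, and the audit hash chain covers
the final container. An external muxer (e.g. FFmpeg for MP4/H.264+AAC
delivery) plugs in behind the same four-argument interface. Post-mux, the
probe must show the source fps and sample rate and an AV duration
difference of at most one frame period, or `muxAV()` errors.

## Quality control

Machine checks are pure readers and never modify media:

* **Tone scan**: a PHI interval is flagged when the fraction of its
  spectral energy within ±30 Hz of the tone frequency falls below 0.6. A
  pure tone concentrates essentially all energy in that band; voiced
  speech spreads it across harmonics, so the margin between the two
  classes is wide and the threshold uncritical.
* **Voice no-op detector**: compares original and scrubbed audio on the
  non-PHI samples; a median-F0 shift under 10% combined with a relative
  waveform RMS difference under 0.1 fails — this is what catches a
  disabled or identity transform.
* **Blur coverage**: per-region variance-reduction ratio
  `1 − var(deid)/var(original)` (0 when the original region is constant)
  with a 0.5 threshold, plus an exact count of changed pixels outside all
  regions, which must be 0 for PPP. The variance proxy for "adequately
  obscured" is a stand-in for human judgment and is labelled as such.
* **Residual-face scan**: a harness around a pluggable detector — any
  detection in output frames flags the frame. No model ships with the
  package, deliberately: automated adversarial face re-detection on
  blurred video is an unsolved problem, so the harness plus a stub is the
  honest deliverable.

Reviewer checklists (four video criteria per mode plus two shared audio
criteria) carry stable rule ids so human findings and machine findings
land in the same report format. The human re-editing loop is represented
only as report states; it is not automated.

## The artifact ledger

Every stage appends one record: stage name, timestamp, a digest of its
parameter block, and content digests of its inputs and outputs (MD5 via
`tools::md5sum`; directories hash as the sorted list of per-file
digests). Inputs must match a prior stage's outputs or a declared
external, so `verifyLedger()` can detect both tampering and provenance
breaks. Timestamps live only in the ledger, never in artifacts, which is
why a rerun with the same config, inputs and seed reproduces every output
hash bit-for-bit. The store is a plain directory; no network is ever
touched.

# The synthetic fixtures

The generator emulates the *statistical challenges* of real recordings,
not their content:

* transcripts with 200–380 ms words, 40–120 ms gaps, 4–8-word segments
  alternating between speakers (interleaved speech), and PHI surface
  forms planted at known positions — defaults plant one roughly every 12
  words, cycling all six categories;
* audio as 8-harmonic "vowels" at each speaker's F0 (defaults 120 and
  180 Hz, whose harmonics all avoid the 440 ± 30 Hz tone band, keeping
  tone and speech spectrally separable) over a seeded noise floor;
* stick-figure clips on a period-1 checkerboard background (every local
  window has positive variance, so blur checks are strict everywhere),
  with piecewise-linear motion, Gaussian detection jitter (σ = 0.5 px)
  and seeded dropout runs bounded by `dropoutMaxGap` — occlusion and
  rapid movement in miniature. The first and last frames never drop, so
  every track has anchoring observations.

Everything is deterministic under the spec seed (sub-generators derive
fixed offsets from it), so fixture sets are byte-identical across runs.

What passing these tests shows: the *mechanisms* are correct — intervals
map and merge exactly, tones land where the transcript says, the disguise
moves F0 by the requested ratio, interpolation and smoothing behave as
specified, blurring is local and covering, the mux preserves rates, the
loop closes with a verifiable ledger. What they cannot show: performance
on real data, where ASR word error, diarization confusion, pose detector
misses on unusual postures, and PHI surface forms outside the rule set
all degrade the input side. Those error sources are upstream properties;
on real recordings the QC stage and a human reviewer remain load-bearing.

# Problem sizes

The shipped suite uses 1000 six-second transcripts for the interval
oracle, 100 seeded buffers for tone scrubbing, a 3 × 3 grid of F0s and
ratios on two-second signals, 100 forty-frame tracks and 50
three-hundred-frame simulations for tracking, 60–20-frame clips at
96 × 128 px for the obscuration checks, and a 30-second two-speaker
900-frame fixture for the end-to-end closed loop in both modes — sizes
chosen so the full property surface runs comfortably on a single CPU
while still exercising every code path at realistic rates.

# Known limitations

* Redaction quality is bounded by the rule set; no statistical NER.
* The irreversibility of the voice transform is a proxy property; formal
  speaker re-identification resistance is not evaluated.
* Track association is greedy; crossing subjects within the distance gate
  can swap identities (flagged only indirectly, via QC).
* On-screen text (ID cards, monitors, documents) is not detected or
  redacted; neither are tattoos or other body marks.
* The built-in container profile is lossless and therefore large;
  compressed delivery requires an external muxer.
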