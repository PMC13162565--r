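# avdeid

De-identification of clinical audio-video recordings in R.

Audio-video recordings of clinical encounters — telemedicine sessions,
training videos, patient-monitoring footage — are full of protected health
information (PHI) that plain-text de-identification tools never touch:
spoken names and dates, the speakers' voices themselves, and the faces and
surroundings visible on camera. `avdeid` is a pipeline for researchers who
need to share such recordings: it removes PHI from the transcript, the
audio track and the video frames, re-synchronizes the streams, and leaves
behind a machine-verifiable audit trail.

## The pipeline

Six stages, each usable on its own or through `runPipeline()`:

1. **Transcript import** — diarized, word-level-timestamped transcripts
   (WhisperX-style JSON) are parsed, validated and flattened to one row per
   word. The word timestamps are the spine that links text redaction to
   audio time.
2. **Transcript redaction** — a rule engine (lexicons for names and
   locations, ordered regex patterns for dates, record numbers, phone
   numbers and ages, a safe list that always wins) marks PHI spans and
   replaces the affected words with placeholders such as `[NAME]`.
   Overlaps resolve deterministically: longest match first, then patterns
   before lexicons, then rule order.
3. **Audio scrubbing** — each redacted span maps to its exact millisecond
   interval `[min start, max end)`; nearby intervals merge (default gap
   50 ms); the samples are replaced by a tone (silence can itself carry
   clinical meaning, so a tone marks the cut). The remaining speech is
   disguised per speaker: the fundamental frequency F0 is scaled by a
   seeded random ratio drawn from [0.7, 0.85] ∪ [1.2, 1.45] and the
   spectral envelope warped, via a phase-vocoder that never changes the
   sample count, so timing survives intact.
4. **Video obscuration** — per-frame 17-keypoint COCO pose detections are
   associated into per-person tracks (greedy nearest-centroid with a
   distance gate), detection gaps are filled by linear interpolation
   (constant extension at the ends, long gaps flagged to QC), and every
   coordinate series is smoothed by a constant-velocity Kalman filter.
   Then either **PPP** (precision mode: Gaussian blur of the facial
   bounding box, hull of the confident facial keypoints plus a 25% margin
   — context preserved) or **GPP** (greedy mode: the whole frame blurred,
   a skeleton overlay drawn on top — everything obscured).
5. **AV synchronization** — stage-logged processing delays give the signed
   offset `audio − video`; the audio is trimmed/padded accordingly and the
   streams are muxed losslessly (uncompressed AVI + PCM written in pure R;
   an external muxer can be plugged in), preserving the source frame rate
   and sampling rate with residual drift below one frame period.
6. **Quality control** — machine checks: a tone-band energy scan of every
   PHI interval, a voice-transform no-op detector, per-region
   variance-reduction blur coverage, pixel-exact locality for PPP, plus a
   pluggable residual-face re-detection harness and mode-specific reviewer
   checklists. Every stage appends a hash-chained record to the artifact
   ledger; `verifyLedger()` detects any post-hoc tampering.

A deterministic synthetic generator (`fixtureSpec()`, `genTranscript()`,
`genAudio()`, `genPoseClip()`) produces transcripts with planted PHI,
harmonic voice-like audio and stick-figure pose clips with known ground
truth, so the whole pipeline is testable without any real recordings or
model weights.

## Worked example

```r
library(avdeid)

spec <- fixtureSpec(seed = 42, durationS = 12)
fx   <- genTranscript(spec)
fx$transcript
#> Transcript: 5 segment(s), 30 word(s), 2 speaker(s), 12000 ms

rows  <- flattenTranscript(fx$transcript)
rules <- fixtureRedactionRules(fx$plan)
(spans <- detectPhi(rows, rules))
#>   word_start_index word_end_index category matched_text          rule_id
#> 1                6              6     NAME     Margaret     name_lexicon
#> 2               18             18 LOCATION    Rivertown location_lexicon

audio <- genAudio(spec, fx$transcript)
scrub <- scrubAudio(audio, fx$transcript, spans,
                    voiceParams = sampleVoiceParams(
                      unique(transcriptWords(fx$transcript)$speaker),
                      seed = 42))
scrub$intervals
#>   start_ms end_ms category source_word_indices
#> 1     2257   2550     NAME                   6
#> 2     6860   7081 LOCATION                  18

c(f0_original = medianF0(audio), f0_disguised = medianF0(scrub$audio))
#>  f0_original f0_disguised
#>     120.2449     243.7254

nrow(residualPhiScan(scrub$audio, scrub$intervals))
#> [1] 0
```

The detector found both planted PHI words; their audio intervals were
replaced by tones (the residual scan finds no remaining speech energy
there), and the speaker's median F0 moved from 120 Hz to 244 Hz — the
voice is disguised while every word keeps its original timing.

The full pipeline runs the same way from a config:

```r
cfg <- pipelineConfig(mode = "PPP", seed = 42, rules = rules)
res <- runPipeline(cfg, list(transcript = fx$transcript, audio = audio,
                             frames = clip$frames,
                             detections = clip$detections, fps = 30),
                   "run_dir")
qcStatus(res$report)   # "pass"
verifyLedger("run_dir")$intact   # TRUE
```

A command-line front end with per-stage subcommands lives at
`inst/cli/avdeid.R`:

```sh
Rscript inst/cli/avdeid.R fixtures --seed 4 --duration 10 --out fx
Rscript inst/cli/avdeid.R run-all --mode GPP --transcript fx/transcript.json \
    --audio fx/audio.wav --frames fx/frames --detections fx/detections.json \
    --rules fx/rules.yaml --fps 30 --out run
Rscript inst/cli/avdeid.R verify --out run
```

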