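test_that("a single-word span maps to that word's exact interval", {
  w <- data.frame(segment = 1L, speaker = "A", start_ms = 67358L,
                  end_ms = 68798L, text = "Margaret", confidence = 1)
  t <- transcriptFromWords(w, durationMs = 70000L)
  spans <- data.frame(word_start_index = 1L, word_end_index = 1L,
                      category = "NAME", matched_text = "Margaret",
                      rule_id = "planted", stringsAsFactors = FALSE)
  iv <- phiIntervals(t, spans)
  expect_identical(iv$start_ms, 67358L)
  expect_identical(iv$end_ms, 68798L)
  expect_equal(phiIntervals(t, spans[0, ]), phiIntervals(t, spans)[0, ],
               ignore_attr = TRUE)
})

test_that("intervals closer than the merge gap fuse into one", {
  w <- data.frame(segment = c(1L, 1L), speaker = "A",
                  start_ms = c(100L, 220L), end_ms = c(200L, 300L),
                  text = c("Anna", "Okafor"), confidence = 1)
  t <- transcriptFromWords(w, durationMs = 1000L)
  spans <- data.frame(word_start_index = 1:2, word_end_index = 1:2,
                      category = "NAME", matched_text = w$text,
                      rule_id = "planted", stringsAsFactors = FALSE)
  iv <- phiIntervals(t, spans, mergeGapMs = 50)
  expect_equal(nrow(iv), 1)
  expect_identical(iv$start_ms, 100L)
  expect_identical(iv$end_ms, 300L)
  expect_equal(iv$source_word_indices, "1,2")
  # gap of exactly the threshold is NOT merged
  iv2 <- phiIntervals(t, spans, mergeGapMs = 20)
  expect_equal(nrow(iv2), 2)
})

test_that("unknown word indices in spans error", {
  t <- genTranscript(fixtureSpec(seed = 1, durationS = 5))$transcript
  spans <- data.frame(word_start_index = 999L, word_end_index = 999L,
                      category = "NAME", matched_text = "x",
                      rule_id = "p", stringsAsFactors = FALSE)
  expect_error(phiIntervals(t, spans), "999")
})

test_that("tone insertion is exact inside and bit-identical outside", {
  sr <- 16000L
  set.seed(42)
  a <- audioBuffer(0.5 * runif(3 * sr, -1, 1), sr)
  iv <- data.frame(start_ms = 1000L, end_ms = 2000L)
  tone <- toneSpec(frequencyHz = 440, amplitude = 0.2, fadeMs = 0)
  out <- insertTones(a, iv, tone)
  expect_equal(length(audioSamples(out)), length(audioSamples(a)))
  n <- 16000:31999
  expect_equal(audioSamples(out)[n + 1], 0.2 * sin(2 * pi * 440 * n / sr))
  expect_identical(audioSamples(out)[-(n + 1)], audioSamples(a)[-(n + 1)])
})

test_that("tone insertion edge cases behave", {
  sr <- 8000L
  a <- audioBuffer(rep(0.1, sr), sr)
  expect_identical(audioSamples(insertTones(a, data.frame(
    start_ms = integer(), end_ms = integer()))), audioSamples(a))
  whole <- insertTones(a, data.frame(start_ms = 0L, end_ms = 1000L),
                       toneSpec(fadeMs = 0))
  n <- 0:(sr - 1)
  expect_equal(audioSamples(whole), 0.2 * sin(2 * pi * 440 * n / sr))
  expect_error(insertTones(a, data.frame(start_ms = 500L, end_ms = 1500L)),
               "exceeds")
  expect_error(insertTones(a, data.frame(start_ms = 0L, end_ms = 100L),
                           toneSpec(frequencyHz = 4500)), "Nyquist")
})

test_that("fades ramp the tone linearly at both edges", {
  sr <- 16000L
  a <- audioBuffer(numeric(sr), sr)
  out <- insertTones(a, data.frame(start_ms = 0L, end_ms = 1000L),
                     toneSpec(frequencyHz = 440, amplitude = 0.5,
                              fadeMs = 10))
  x <- audioSamples(out)
  nf <- 160
  n <- 0:(sr - 1)
  pure <- 0.5 * sin(2 * pi * 440 * n / sr)
  env <- pmin(1, (n + 1) / nf, (sr - n) / nf)
  expect_equal(x, pure * env)
})

test_that("F0 estimator recovers known signals", {
  sr <- 16000L
  sine <- audioBuffer(0.5 * sin(2 * pi * 200 * (0:(sr - 1)) / sr), sr)
  tr <- estimateF0Track(sine)
  expect_true(all(tr$voiced))
  expect_true(all(abs(tr$f0_hz - 200) <= 2))
  silence <- audioBuffer(numeric(sr), sr)
  expect_false(any(estimateF0Track(silence)$voiced))
  set.seed(7)
  noise <- audioBuffer(0.1 * rnorm(sr), sr)
  expect_lt(mean(estimateF0Track(noise)$voiced), 0.2)
})

test_that("voice transform scales F0 and conserves length", {
  a <- makeHarmonic(120)
  out <- transformVoice(a, voiceTransformParams(f0Ratio = 1.5))
  expect_equal(length(audioSamples(out)), length(audioSamples(a)))
  f0 <- medianF0(out)
  expect_gte(f0, 171); expect_lte(f0, 189)
})

test_that("identity parameters reproduce the input closely", {
  a <- makeHarmonic(120, durS = 1)
  out <- transformVoice(a, voiceTransformParams(1, 1))
  rel <- sqrt(mean((audioSamples(out) - audioSamples(a))^2)) /
    sqrt(mean(audioSamples(a)^2))
  expect_lte(rel, 0.05)
})

test_that("silent input is returned unchanged with a warning", {
  a <- audioBuffer(numeric(8000), 8000L)
  expect_warning(out <- transformVoice(a, voiceTransformParams(1.3)),
                 "silent")
  expect_identical(audioSamples(out), audioSamples(a))
})

test_that("the inverse ratio does not restore a word-structured waveform", {
  spec <- fixtureSpec(seed = 5, durationS = 3)
  tr <- genTranscript(spec)
  a <- genAudio(spec, tr$transcript)
  fwd <- transformVoice(a, voiceTransformParams(f0Ratio = 1.3))
  back <- transformVoice(fwd, voiceTransformParams(f0Ratio = 1 / 1.3))
  rel <- sqrt(mean((audioSamples(back) - audioSamples(a))^2)) /
    sqrt(mean(audioSamples(a)^2))
  expect_gt(rel, 0.1)
})

test_that("randomized per-speaker draws are seeded, reproducible and avoid identity", {
  p1 <- sampleVoiceParams(c("A", "B"), seed = 11)
  p2 <- sampleVoiceParams(c("B", "A"), seed = 11)
  expect_identical(p1, p2)
  p3 <- sampleVoiceParams(c("A", "B"), seed = 12)
  expect_false(identical(p1$A$f0Ratio, p3$A$f0Ratio))
  for (s in 1:20) {
    p <- sampleVoiceParams("A", seed = s)$A
    expect_true(p$f0Ratio <= 0.85 || p$f0Ratio >= 1.2)
    expect_true(p$f0Ratio >= 0.7 && p$f0Ratio <= 1.45)
  }
})

test_that("scrubbed fixtures carry tones in every planted interval", {
  spec <- fixtureSpec(seed = 21, durationS = 8)
  tr <- genTranscript(spec)
  a <- genAudio(spec, tr$transcript)
  sc <- scrubAudio(a, tr$transcript, tr$spans,
                   voiceParams = sampleVoiceParams(
                     unique(transcriptWords(tr$transcript)$speaker),
                     seed = 3))
  expect_equal(length(audioSamples(sc$audio)), length(audioSamples(a)))
  expect_equal(nrow(residualPhiScan(sc$audio, sc$intervals)), 0)
  # unscrubbed audio fails the same scan in every interval
  expect_equal(nrow(residualPhiScan(a, sc$intervals)), nrow(sc$intervals))
})
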