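test_that("fixtures are byte-identical under a fixed seed", {
  s1 <- fixtureSpec(seed = 8, durationS = 4, nFrames = 10)
  s2 <- fixtureSpec(seed = 8, durationS = 4, nFrames = 10)
  t1 <- genTranscript(s1); t2 <- genTranscript(s2)
  expect_identical(t1, t2)
  expect_identical(genAudio(s1, t1$transcript)@samples,
                   genAudio(s2, t2$transcript)@samples)
  c1 <- genPoseClip(s1); c2 <- genPoseClip(s2)
  expect_identical(c1$frames, c2$frames)
  expect_identical(c1$detections, c2$detections)
  # a different seed changes the content
  expect_false(identical(genTranscript(fixtureSpec(seed = 9, durationS = 4)),
                         t1))
})

test_that("planted PHI appears exactly at the planned positions", {
  plan <- data.frame(position = c(3L, 9L), category = c("NAME", "DATE"),
                     surface = c("Okafor", "03/14/2019"),
                     stringsAsFactors = FALSE)
  tr <- genTranscript(fixtureSpec(seed = 2, durationS = 6, phiPlan = plan))
  w <- transcriptWords(tr$transcript)
  expect_equal(w$text[3], "Okafor")
  expect_equal(w$text[9], "03/14/2019")
  expect_equal(nrow(tr$spans), 2)
  # infeasible plans error
  badPlan <- data.frame(position = 10000L, category = "NAME",
                        surface = "x", stringsAsFactors = FALSE)
  expect_error(genTranscript(fixtureSpec(seed = 2, durationS = 6,
                                         phiPlan = badPlan)), "position")
})

test_that("the matched rule set recovers exactly the ground-truth spans", {
  for (seed in c(1, 5, 23)) {
    tr <- genTranscript(fixtureSpec(seed = seed, durationS = 20))
    rows <- flattenTranscript(tr$transcript)
    got <- detectPhi(rows, fixtureRedactionRules(tr$plan))
    expect_identical(got[, c("word_start_index", "word_end_index",
                             "category")],
                     tr$spans[, c("word_start_index", "word_end_index",
                                  "category")],
                     label = paste("seed", seed))
  }
})

test_that("generated audio carries each speaker's F0 in its word intervals", {
  spec <- fixtureSpec(seed = 6, durationS = 10, f0PerSpeaker = c(120, 180))
  tr <- genTranscript(spec)
  a <- genAudio(spec, tr$transcript)
  w <- transcriptWords(tr$transcript)
  sr <- spec$sampleRateHz
  speakers <- sort(unique(w$speaker))
  for (si in seq_along(speakers)) {
    ws <- w[w$speaker == speakers[si], ][1:3, ]
    est <- vapply(seq_len(nrow(ws)), function(i) {
      n0 <- round(ws$start_ms[i] * sr / 1000)
      n1 <- round(ws$end_ms[i] * sr / 1000)
      medianF0(audioBuffer(a@samples[(n0 + 1):n1], sr), frameMs = 30)
    }, 0)
    expect_true(all(abs(est - spec$f0PerSpeaker[si]) <= 3),
                label = sprintf("speaker %s F0", speakers[si]))
  }
  expect_equal(length(a@samples), spec$durationS * sr)
})

test_that("a wordless transcript gives a noise-floor-only buffer", {
  spec <- fixtureSpec(seed = 3, durationS = 2)
  empty <- new("Transcript", durationMs = 2000L)
  a <- genAudio(spec, empty)
  expect_equal(length(a@samples), 32000)
  expect_lt(max(abs(a@samples)), 0.02)
})

test_that("dropouts are bounded and absent from first and last frames", {
  spec <- fixtureSpec(seed = 17, durationS = 2, nFrames = 80,
                      dropoutRate = 0.15, dropoutMaxGap = 4)
  clip <- genPoseClip(spec)
  d <- clip$droppedFrames[[1]]
  expect_false(d[1]); expect_false(d[80])
  runs <- rle(d)
  expect_lte(max(runs$lengths[runs$values]), 4)
  # detections exist exactly on non-dropped frames
  hasDet <- vapply(clip$detections, function(f) length(f$persons) > 0, TRUE)
  expect_identical(hasDet, !d)
})

test_that("a written fixture set re-reads through the pipeline formats", {
  d <- withr::local_tempdir()
  spec <- fixtureSpec(seed = 12, durationS = 3, nFrames = 8)
  writeFixture(spec, d)
  expect_true(all(file.exists(file.path(d, c(
    "transcript.json", "audio.wav", "detections.json",
    "ground_truth.json", "rules.yaml")))))
  t <- parseTranscript(file.path(d, "transcript.json"))
  expect_gt(nWords(t), 0)
  a <- readWav(file.path(d, "audio.wav"))
  expect_equal(sampleRate(a), spec$sampleRateHz)
  det <- parseDetections(file.path(d, "detections.json"))
  expect_length(det, 8)
  frames <- readFrames(file.path(d, "frames"))
  expect_length(frames, 8)
  rules <- readRedactionRules(file.path(d, "rules.yaml"))
  expect_s4_class(rules, "RedactionRules")
})

test_that("WAV files round-trip in both supported encodings", {
  set.seed(2)
  a <- audioBuffer(round(runif(5000, -0.9, 0.9), 4), 22050L)
  f16 <- withr::local_tempfile(fileext = ".wav")
  writeWav(a, f16, "pcm16")
  b <- readWav(f16)
  expect_equal(sampleRate(b), 22050L)
  expect_equal(audioSamples(b), audioSamples(a), tolerance = 1e-4)
  f32 <- withr::local_tempfile(fileext = ".wav")
  writeWav(a, f32, "float32")
  c32 <- readWav(f32)
  expect_equal(audioSamples(c32), audioSamples(a), tolerance = 1e-7)
})
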