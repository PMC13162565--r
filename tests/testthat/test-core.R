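smallPipelineFixture <- function(seed = 11) {
  spec <- fixtureSpec(seed = seed, durationS = 4, nFrames = 40, fps = 10)
  tr <- genTranscript(spec)
  list(spec = spec, tr = tr,
       inputs = list(transcript = tr$transcript,
                     audio = genAudio(spec, tr$transcript),
                     frames = genPoseClip(spec)$frames,
                     detections = genPoseClip(spec)$detections,
                     fps = 10))
}

test_that("invalid configurations are rejected before any stage runs", {
  cfg <- pipelineConfig(mode = "GPP")
  cfg$mode <- "SNEAKY"
  expect_error(validatePipelineConfig(cfg), "unknown privacy mode")
  cfg2 <- pipelineConfig(mode = "PPP")
  cfg2$avsync$policy <- "stretch"
  expect_error(validatePipelineConfig(cfg2), "policy")
  fx <- smallPipelineFixture()
  d <- withr::local_tempdir()
  expect_error(runPipeline(cfg, fx$inputs, file.path(d, "bad")),
               "unknown privacy mode")
  expect_false(file.exists(file.path(d, "bad", "ledger.jsonl")))
})

test_that("a full run produces all artifacts, a report and an intact ledger", {
  fx <- smallPipelineFixture()
  cfg <- pipelineConfig(mode = "GPP", seed = 2,
                        rules = fixtureRedactionRules(fx$tr$plan))
  d <- withr::local_tempdir()
  res <- runPipeline(cfg, fx$inputs, file.path(d, "run"))
  expect_s4_class(res$report, "QCReport")
  expect_equal(qcStatus(res$report), "pass")
  expect_true(file.exists(res$container))
  expect_true(all(file.exists(file.path(res$outDir, c(
    "transcript.json", "redacted.csv", "redaction_map.json",
    "audio_deid.wav", "phi_intervals.json", "deid.avi",
    "qc_report.json", "ledger.jsonl")))))
  ledger <- readLines(res$ledger)
  expect_length(ledger, 6)
  stages <- vapply(ledger, function(l)
    jsonlite::fromJSON(l)$stage, "", USE.NAMES = FALSE)
  expect_identical(stages, c("transcript_import", "redact", "audioscrub",
                             "videodeid", "avsync", "qc"))
  v <- verifyLedger(res$outDir)
  expect_true(v$intact)
  expect_false(v$empty)
})

test_that("rerunning with identical config and inputs reproduces every hash", {
  fx <- smallPipelineFixture()
  cfg <- pipelineConfig(mode = "PPP", seed = 4,
                        rules = fixtureRedactionRules(fx$tr$plan))
  d <- withr::local_tempdir()
  r1 <- runPipeline(cfg, fx$inputs, file.path(d, "a"))
  r2 <- runPipeline(cfg, fx$inputs, file.path(d, "b"))
  expect_identical(r1$outputHashes, r2$outputHashes)
})

test_that("tampering with an intermediate is flagged by ledger verification", {
  fx <- smallPipelineFixture()
  cfg <- pipelineConfig(mode = "GPP", seed = 2,
                        rules = fixtureRedactionRules(fx$tr$plan))
  d <- withr::local_tempdir()
  res <- runPipeline(cfg, fx$inputs, file.path(d, "run"))
  writeLines("tampered", file.path(res$outDir, "redacted.csv"))
  v <- verifyLedger(res$outDir)
  expect_false(v$intact)
  expect_true(any(v$breaks$name == "redacted.csv"))
  # a directory with no ledger is intact-but-empty
  v0 <- verifyLedger(withr::local_tempdir())
  expect_true(v0$intact); expect_true(v0$empty)
})

test_that("a stage failure names the stage and preserves prior artifacts", {
  fx <- smallPipelineFixture()
  cfg <- pipelineConfig(mode = "GPP", seed = 2,
                        rules = fixtureRedactionRules(fx$tr$plan))
  fx$inputs$detections <- list(list(frame = 999L, persons = list()))
  d <- withr::local_tempdir()
  expect_error(runPipeline(cfg, fx$inputs, file.path(d, "run")),
               "stage 'videodeid'")
  # stages 1-3 completed and their artifacts survive
  expect_true(file.exists(file.path(d, "run", "audio_deid.wav")))
  ledger <- readLines(file.path(d, "run", "ledger.jsonl"))
  last <- jsonlite::fromJSON(ledger[length(ledger)])
  expect_equal(last$stage, "videodeid")
  expect_equal(last$status, "error")
})
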