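#' Pipeline configuration
#'
#' One validated record holding every stage's parameters. Stage parameter
#' blocks are hashed into the artifact ledger, so a run is reproducible
#' from its config and inputs alone.
#'
#' @param mode privacy mode, "PPP" or "GPP"
#' @param seed master seed for all randomized steps (voice parameter draws)
#' @param rules a [RedactionRules-class], or a path to a rule file for
#'   [readRedactionRules()]
#' @param tone a [toneSpec()]
#' @param voice list: enabled (logical), scope ("speaker": one seeded draw
#'   per speaker label; "file": one draw for the whole track),
#'   ratioRanges, envWarpRange (see [sampleVoiceParams()])
#' @param video a [privacyModeParams()]; its mode is forced to `mode`
#' @param avsync list: policy ("pad" or "trim")
#' @param qc list: toneBandThreshold, toneBandWidthHz, minCoverageRatio,
#'   gppSampleEvery (frame sampling stride for the GPP blur check)
#' @param mergeGapMs PHI interval merge gap, ms
#' @export
pipelineConfig <- function(mode = c("GPP", "PPP"), seed = 1L, rules = NULL,
                           tone = toneSpec(),
                           voice = list(enabled = TRUE, scope = "speaker"),
                           video = NULL,
                           avsync = list(policy = "pad"),
                           qc = list(), mergeGapMs = 50) {
  mode <- match.arg(mode)
  if (is.character(rules)) rules <- readRedactionRules(rules)
  if (is.null(rules)) rules <- redactionRules()
  if (is.null(video)) video <- privacyModeParams(mode)
  video$mode <- mode
  voice <- utils::modifyList(
    list(enabled = TRUE, scope = "speaker",
         ratioRanges = list(c(0.7, 0.85), c(1.2, 1.45)),
         envWarpRange = c(0.9, 1.1)), voice)
  qc <- utils::modifyList(
    list(toneBandThreshold = 0.6, toneBandWidthHz = 30,
         minCoverageRatio = 0.5, gppSampleEvery = 10L), qc)
  cfg <- structure(list(mode = mode, seed = as.integer(seed), rules = rules,
                        tone = tone, voice = voice, video = video,
                        avsync = avsync, qc = qc,
                        mergeGapMs = mergeGapMs),
                   class = "pipelineConfig")
  validatePipelineConfig(cfg)
  cfg
}

#' Validate a pipeline configuration
#'
#' Runs before any stage executes; an invalid config never starts stage 1.
#' @param cfg a [pipelineConfig()]
#' @export
validatePipelineConfig <- function(cfg) {
  if (!inherits(cfg, "pipelineConfig"))
    stop("not a pipelineConfig", call. = FALSE)
  if (!cfg$mode %in% c("PPP", "GPP"))
    stop("unknown privacy mode: ", cfg$mode, call. = FALSE)
  if (!is(cfg$rules, "RedactionRules")) stop("rules must be a RedactionRules",
                                             call. = FALSE)
  validObject(cfg$rules)
  if (!inherits(cfg$tone, "toneSpec")) stop("tone must be a toneSpec",
                                            call. = FALSE)
  if (!cfg$voice$scope %in% c("speaker", "file"))
    stop("voice scope must be 'speaker' or 'file'", call. = FALSE)
  if (!cfg$avsync$policy %in% c("pad", "trim"))
    stop("avsync policy must be 'pad' or 'trim'", call. = FALSE)
  invisible(TRUE)
}

# Content digest of a file, or of a directory (sorted per-file digests
# hashed together).
pathDigest <- function(path) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, recursive = TRUE, full.names = TRUE))
    lines <- vapply(files, function(f)
      paste0(basename(f), ":", fileDigest(f)), "")
    return(objectDigest(unname(lines)))
  }
  fileDigest(path)
}

configHashable <- function(cfg) {
  r <- cfg$rules
  list(mode = cfg$mode, seed = cfg$seed,
       rules = list(name = r@nameLexicon, location = r@locationLexicon,
                    safe = r@safeLexicon, patterns = r@patterns,
                    style = r@placeholderStyle),
       tone = unclass(cfg$tone), voice = cfg$voice,
       video = unclass(cfg$video), avsync = cfg$avsync, qc = cfg$qc,
       mergeGapMs = cfg$mergeGapMs)
}

appendLedger <- function(ledgerPath, stage, params, inputs, outputs,
                         status = "ok", externals = character()) {
  rec <- list(stage = stage,
              timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%OS3%z"),
              params_hash = objectDigest(params),
              inputs = as.list(inputs), outputs = as.list(outputs),
              externals = as.list(externals), status = status)
  cat(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA, null = "null"),
      "\n", sep = "", file = ledgerPath, append = TRUE)
  invisible(rec)
}

#' Verify an artifact ledger against the run directory
#'
#' Recomputes the content digest of every surviving artifact and checks the
#' hash chain: each stage's inputs must match some prior stage's outputs or
#' a declared external. Returns a verdict rather than erroring.
#'
#' @param dir pipeline run directory containing `ledger.jsonl`
#' @return list: intact (logical), empty (logical), breaks (data.frame:
#'   stage, name, reason)
#' @export
verifyLedger <- function(dir) {
  ledgerPath <- file.path(dir, "ledger.jsonl")
  breaks <- list()
  addBreak <- function(stage, name, reason)
    breaks[[length(breaks) + 1L]] <<- data.frame(
      stage = stage, name = name, reason = reason, stringsAsFactors = FALSE)
  if (!file.exists(ledgerPath) || !length(readLines(ledgerPath)))
    return(list(intact = TRUE, empty = TRUE,
                breaks = data.frame(stage = character(), name = character(),
                                    reason = character())))
  lines <- readLines(ledgerPath)
  seen <- character()
  for (ln in lines) {
    rec <- jsonlite::fromJSON(ln, simplifyVector = FALSE)
    for (nm in names(rec$externals)) seen <- c(seen, rec$externals[[nm]])
    for (nm in names(rec$inputs)) {
      if (!rec$inputs[[nm]] %in% seen)
        addBreak(rec$stage, nm, "input hash matches no prior output")
    }
    for (nm in names(rec$outputs)) {
      p <- file.path(dir, nm)
      if (!file.exists(p) && !dir.exists(p)) {
        addBreak(rec$stage, nm, "artifact missing")
      } else if (!identical(pathDigest(p), rec$outputs[[nm]])) {
        addBreak(rec$stage, nm, "artifact content differs from ledger hash")
      }
      seen <- c(seen, rec$outputs[[nm]])
    }
  }
  breaks <- if (length(breaks)) do.call(rbind, breaks) else
    data.frame(stage = character(), name = character(),
               reason = character(), stringsAsFactors = FALSE)
  list(intact = !nrow(breaks), empty = FALSE, breaks = breaks)
}

materializeInputs <- function(inputs, dir) {
  inDir <- file.path(dir, "inputs")
  dir.create(inDir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  tr <- inputs$transcript
  paths$transcript <- file.path(inDir, "transcript.json")
  if (is(tr, "Transcript")) serializeTranscript(tr, paths$transcript)
  else file.copy(tr, paths$transcript, overwrite = TRUE)
  au <- inputs$audio
  paths$audio <- file.path(inDir, "audio.wav")
  if (is(au, "AudioBuffer")) writeWav(au, paths$audio)
  else file.copy(au, paths$audio, overwrite = TRUE)
  fr <- inputs$frames
  paths$frames <- file.path(inDir, "frames")
  if (is.list(fr)) writeFrames(fr, paths$frames)
  else {
    dir.create(paths$frames, showWarnings = FALSE)
    file.copy(list.files(fr, full.names = TRUE), paths$frames,
              overwrite = TRUE)
  }
  de <- inputs$detections
  paths$detections <- file.path(inDir, "detections.json")
  if (is.list(de)) writeDetections(de, paths$detections)
  else file.copy(de, paths$detections, overwrite = TRUE)
  paths
}

stageFail <- function(ledgerPath, stage, params, e) {
  appendLedger(ledgerPath, stage, params, list(), list(), status = "error")
  stop(sprintf("pipeline stage '%s' failed: %s", stage,
               conditionMessage(e)), call. = FALSE)
}

#' Run the full de-identification pipeline
#'
#' Executes the six stages in order — transcript import, transcript
#' redaction, audio scrubbing, video de-identification, AV synchronization,
#' QC — persisting every intermediate under `outDir` with a hash-chained
#' [appendLedger()] record per stage. A failure at any stage leaves prior
#' artifacts and the ledger intact.
#'
#' @param config a [pipelineConfig()]
#' @param inputs list: transcript ([Transcript-class] or JSON path), audio
#'   ([AudioBuffer-class] or WAV path), frames (list of frames or PNG
#'   directory), detections (detection list or JSON path), fps (frame rate)
#' @param outDir run directory (created; must be empty or absent)
#' @return list: outDir, container (AVI path), report ([QCReport-class]),
#'   ledger (ledger path), outputHashes (named digests of final artifacts)
#' @export
runPipeline <- function(config, inputs, outDir) {
  validatePipelineConfig(config)
  stopifnot(!is.null(inputs$fps))
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  ledgerPath <- file.path(outDir, "ledger.jsonl")
  if (file.exists(ledgerPath)) unlink(ledgerPath)
  cfgHash <- configHashable(config)
  rel <- function(p) sub(paste0("^", normalizePath(outDir), "/"), "",
                         normalizePath(p))

  paths <- materializeInputs(inputs, outDir)
  externalHashes <- vapply(paths, pathDigest, "")
  names(externalHashes) <- paste0("inputs/", basename(unlist(paths)))

  # Stage 1: transcript import -------------------------------------------
  stage <- "transcript_import"
  res <- tryCatch({
    t <- parseTranscript(paths$transcript)
    out <- file.path(outDir, "transcript.json")
    serializeTranscript(t, out)
    appendLedger(ledgerPath, stage, cfgHash["seed"],
                 inputs = c(transcript = unname(
                   externalHashes["inputs/transcript.json"])),
                 outputs = c("transcript.json" = pathDigest(out)),
                 externals = externalHashes)
    t
  }, error = function(e) stageFail(ledgerPath, stage, cfgHash, e))
  transcript <- res

  # Stage 2: transcript redaction ----------------------------------------
  stage <- "redact"
  res <- tryCatch({
    rows <- flattenTranscript(transcript)
    spans <- detectPhi(rows, config$rules)
    red <- applyRedaction(rows, spans, config$rules)
    csv <- file.path(outDir, "redacted.csv")
    writeFlattened(red$rows, csv)
    mapPath <- file.path(outDir, "redaction_map.json")
    writeLines(jsonlite::toJSON(red$map, dataframe = "rows",
                                auto_unbox = TRUE, digits = NA), mapPath)
    appendLedger(ledgerPath, stage, cfgHash$rules,
                 inputs = c("transcript.json" = pathDigest(
                   file.path(outDir, "transcript.json"))),
                 outputs = c("redacted.csv" = pathDigest(csv),
                             "redaction_map.json" = pathDigest(mapPath)))
    list(spans = spans, rows = red$rows)
  }, error = function(e) stageFail(ledgerPath, stage, cfgHash, e))
  spans <- res$spans

  # Stage 3: audio scrubbing ---------------------------------------------
  stage <- "audioscrub"
  res <- tryCatch({
    a <- readWav(paths$audio)
    vp <- if (!config$voice$enabled) NULL
      else if (config$voice$scope == "file")
        sampleVoiceParams("track", seed = config$seed,
                          ratioRanges = config$voice$ratioRanges,
                          envWarpRange = config$voice$envWarpRange)[[1]]
      else
        sampleVoiceParams(unique(transcriptWords(transcript)$speaker),
                          seed = config$seed,
                          ratioRanges = config$voice$ratioRanges,
                          envWarpRange = config$voice$envWarpRange)
    sc <- scrubAudio(a, transcript, spans, tone = config$tone,
                     voiceParams = vp, mergeGapMs = config$mergeGapMs)
    wavPath <- file.path(outDir, "audio_deid.wav")
    writeWav(sc$audio, wavPath)
    intPath <- file.path(outDir, "phi_intervals.json")
    writeLines(jsonlite::toJSON(sc$intervals, dataframe = "rows",
                                auto_unbox = TRUE, digits = NA), intPath)
    appendLedger(ledgerPath, stage,
                 list(tone = unclass(config$tone), voice = config$voice,
                      mergeGapMs = config$mergeGapMs, seed = config$seed),
                 inputs = c(audio = unname(
                   externalHashes["inputs/audio.wav"])),
                 outputs = c("audio_deid.wav" = pathDigest(wavPath),
                             "phi_intervals.json" = pathDigest(intPath)))
    list(audio = sc$audio, intervals = sc$intervals, original = a)
  }, error = function(e) stageFail(ledgerPath, stage, cfgHash, e))
  scrub <- res

  # Stage 4: video de-identification -------------------------------------
  stage <- "videodeid"
  res <- tryCatch({
    frames <- readFrames(paths$frames)
    detections <- parseDetections(paths$detections)
    pv <- processVideo(frames, detections, config$video)
    frameDir <- file.path(outDir, "frames_deid")
    writeFrames(pv$frames, frameDir)
    regPath <- file.path(outDir, "regions.jsonl")
    writeLines(vapply(seq_len(max(1, nrow(pv$regions))), function(i) {
      if (!nrow(pv$regions)) return("")
      as.character(jsonlite::toJSON(as.list(pv$regions[i, ]),
                                    auto_unbox = TRUE, digits = NA))
    }, ""), regPath)
    appendLedger(ledgerPath, stage, unclass(config$video),
                 inputs = c(frames = unname(externalHashes["inputs/frames"]),
                            detections = unname(
                              externalHashes["inputs/detections.json"])),
                 outputs = c("frames_deid" = pathDigest(frameDir),
                             "regions.jsonl" = pathDigest(regPath)))
    list(frames = pv$frames, regions = pv$regions, tracks = pv$tracks,
         flags = pv$flags, original = frames)
  }, error = function(e) stageFail(ledgerPath, stage, cfgHash, e))
  video <- res

  # Stage 5: AV synchronization ------------------------------------------
  stage <- "avsync"
  res <- tryCatch({
    # Tone insertion, voice transformation and blurring all conserve
    # durations, so the stage-logged intrinsic delays are zero; the
    # mechanism still runs so externally induced delays propagate.
    offset <- computeOffset(
      streamTiming("audio", 0L, sampleRateHz = sampleRate(scrub$audio)),
      streamTiming("video", 0L, fps = inputs$fps))
    avi <- file.path(outDir, "deid.avi")
    mx <- muxAV(video$frames, scrub$audio, inputs$fps, avi,
                offsetMs = offset, policy = config$avsync$policy)
    appendLedger(ledgerPath, stage,
                 list(offsetMs = offset, policy = config$avsync$policy,
                      fps = inputs$fps),
                 inputs = c("audio_deid.wav" = pathDigest(
                              file.path(outDir, "audio_deid.wav")),
                            "frames_deid" = pathDigest(
                              file.path(outDir, "frames_deid"))),
                 outputs = c("deid.avi" = pathDigest(avi)))
    mx
  }, error = function(e) stageFail(ledgerPath, stage, cfgHash, e))
  mux <- res

  # Stage 6: QC ----------------------------------------------------------
  stage <- "qc"
  report <- tryCatch({
    findings <- emptyFindings()
    resid <- residualPhiScan(scrub$audio, scrub$intervals, config$tone,
                             threshold = config$qc$toneBandThreshold,
                             bandWidthHz = config$qc$toneBandWidthHz)
    for (i in seq_len(nrow(resid)))
      findings <- rbind(findings, qcFinding(
        "audio", sprintf("[%d,%d)ms", resid$start_ms[i], resid$end_ms[i]),
        "audio.phi_tones", "fail",
        sprintf("speech energy remains in PHI interval (tone-band %.2f)",
                resid$tone_band_fraction[i])))
    findings <- rbind(findings,
                      qcVoiceTransform(scrub$original, scrub$audio,
                                       excludeIntervals = scrub$intervals))
    if (config$mode == "PPP") {
      for (fi in seq_along(video$frames)) {
        regs <- video$regions[video$regions$frame == fi - 1L, ,
                              drop = FALSE]
        boxes <- lapply(seq_len(nrow(regs)), function(i)
          c(x0 = regs$x0[i], y0 = regs$y0[i], x1 = regs$x1[i],
            y1 = regs$y1[i]))
        met <- blurCoverageMetric(video$original[[fi]], video$frames[[fi]],
                                  boxes)
        if (met$outsideChanges > 0)
          findings <- rbind(findings, qcFinding(
            "video", fi - 1L, "ppp.no_outside_identifiers", "fail",
            sprintf("%d pixel(s) changed outside blur regions",
                    met$outsideChanges)))
        low <- which(met$ratios < config$qc$minCoverageRatio)
        for (i in low)
          findings <- rbind(findings, qcFinding(
            "video", fi - 1L, "ppp.face_obscured", "fail",
            sprintf("blur coverage ratio %.2f below threshold in region %d",
                    met$ratios[i], i)))
      }
    } else {
      sampleIdx <- seq(1, length(video$frames),
                       by = config$qc$gppSampleEvery)
      for (fi in sampleIdx) {
        fs <- frameSizeOf(video$original[[fi]])
        whole <- list(c(x0 = 0, y0 = 0, x1 = fs[2], y1 = fs[1]))
        met <- blurCoverageMetric(video$original[[fi]], video$frames[[fi]],
                                  whole)
        if (met$ratios[1] < config$qc$minCoverageRatio)
          findings <- rbind(findings, qcFinding(
            "video", fi - 1L, "gpp.uniform_blur", "fail",
            sprintf("frame variance reduction %.2f below threshold",
                    met$ratios[1])))
      }
    }
    for (i in seq_len(nrow(video$flags)))
      findings <- rbind(findings, qcFinding(
        "video", video$flags$frame[i],
        if (video$flags$reason[i] == "no_face_bbox") "ppp.face_obscured"
        else "ppp.tracking",
        "warn", sprintf("track %d: %s", video$flags$track[i],
                        video$flags$reason[i])))
    rep <- compileReport(findings, config$mode)
    repPath <- file.path(outDir, "qc_report.json")
    writeQCReport(rep, repPath)
    appendLedger(ledgerPath, stage, config$qc,
                 inputs = c("deid.avi" = pathDigest(
                   file.path(outDir, "deid.avi"))),
                 outputs = c("qc_report.json" = pathDigest(repPath)))
    rep
  }, error = function(e) stageFail(ledgerPath, stage, cfgHash, e))

  finals <- c("transcript.json", "redacted.csv", "redaction_map.json",
              "audio_deid.wav", "phi_intervals.json", "frames_deid",
              "deid.avi", "qc_report.json")
  hashes <- vapply(finals, function(f) pathDigest(file.path(outDir, f)), "")
  list(outDir = outDir, container = mux$path, report = report,
       ledger = ledgerPath, outputHashes = hashes)
}
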