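# Deterministic synthetic fixtures: transcripts with planted PHI, harmonic
# voice-like audio, and stick-figure pose clips with known ground truth.
# They emulate the statistical challenges of real recordings (interleaved
# speakers, detection dropout runs, piecewise-linear motion) without any
# clinical content, so every stage is testable offline.

FIXTURE_VOCAB <- c(
  "so", "we", "are", "back", "again", "the", "doctor", "will", "see",
  "you", "now", "please", "tell", "me", "about", "your", "pain", "today",
  "it", "started", "last", "week", "and", "gets", "worse", "at", "night",
  "take", "a", "deep", "breath", "any", "allergies", "to", "medication",
  "blood", "pressure", "looks", "stable", "follow", "up", "in", "two",
  "weeks", "that", "sounds", "good", "thank", "rest", "well")

FIXTURE_SURFACES <- list(
  NAME = c("Margaret", "Okafor", "Delacroix"),
  LOCATION = c("Springfield", "Rivertown"),
  DATE = c("03/14/2019", "11/02/21"),
  ID = c("MRN483920", "MRN771205"),
  CONTACT = c("555-0147", "555-8822"),
  AGE = c("87-year-old", "42-year-old"))

#' Fixture specification
#'
#' All generator inputs in one record; the same spec and seed always yield
#' byte-identical fixtures.
#'
#' @param seed master seed (sub-generators derive fixed offsets from it)
#' @param durationS audio/transcript duration in seconds
#' @param fps video frame rate
#' @param sampleRateHz audio sampling rate
#' @param nSpeakers number of interleaved speakers
#' @param f0PerSpeaker fundamental frequency (Hz) per speaker
#' @param phiPlan NULL for the default plan (a PHI word roughly every 12
#'   words, cycling categories), or a data.frame (position, category,
#'   surface)
#' @param nFrames video clip length in frames (default `durationS * fps`)
#' @param frameSize video (height, width) in pixels
#' @param nPersons number of stick figures
#' @param personHeightPx figure height in pixels
#' @param dropoutRate per-frame probability that a detection dropout run
#'   starts
#' @param dropoutMaxGap longest dropout run, frames
#' @param jitterSd detection jitter standard deviation, pixels
#' @export
fixtureSpec <- function(seed = 1L, durationS = 30, fps = 30,
                        sampleRateHz = 16000L, nSpeakers = 2L,
                        f0PerSpeaker = c(120, 180), phiPlan = NULL,
                        nFrames = NULL, frameSize = c(96L, 128L),
                        nPersons = 1L, personHeightPx = 64,
                        dropoutRate = 0.05, dropoutMaxGap = 5L,
                        jitterSd = 0.5) {
  stopifnot(durationS > 0, fps > 0, sampleRateHz > 0,
            length(f0PerSpeaker) >= nSpeakers)
  structure(list(seed = as.integer(seed), durationS = durationS, fps = fps,
                 sampleRateHz = as.integer(sampleRateHz),
                 nSpeakers = as.integer(nSpeakers),
                 f0PerSpeaker = f0PerSpeaker, phiPlan = phiPlan,
                 nFrames = if (is.null(nFrames)) round(durationS * fps)
                           else as.integer(nFrames),
                 frameSize = as.integer(frameSize),
                 nPersons = as.integer(nPersons),
                 personHeightPx = personHeightPx,
                 dropoutRate = dropoutRate,
                 dropoutMaxGap = as.integer(dropoutMaxGap),
                 jitterSd = jitterSd),
            class = "fixtureSpec")
}

#' Generate a diarized transcript with planted PHI
#'
#' Words get contiguous, non-overlapping timestamps (word length 200-380 ms,
#' inter-word gap 40-120 ms), grouped into 4-8 word segments that alternate
#' among the speakers. PHI surface forms are planted exactly at the planned
#' word positions; ground-truth spans are returned alongside.
#'
#' @param spec a [fixtureSpec()]
#' @return list: transcript ([Transcript-class]), spans (ground-truth PHI
#'   span table), plan (the phi plan used)
#' @export
genTranscript <- function(spec) {
  stopifnot(inherits(spec, "fixtureSpec"))
  durationMs <- roundHalfUp(spec$durationS * 1000)
  withSeed(spec$seed, {
    nMax <- ceiling(durationMs / 240) + 8L
    wordMs <- roundHalfUp(stats::runif(nMax, 200, 380))
    gapMs <- roundHalfUp(stats::runif(nMax, 40, 120))
    starts <- 150L + c(0L, cumsum(wordMs + gapMs))[seq_len(nMax)]
    ends <- starts + wordMs
    n <- sum(ends <= durationMs - 100L)
    if (n < 1) stop("duration too short for any word", call. = FALSE)
    segLens <- sample(4:8, ceiling(n / 4) + 1L, replace = TRUE)
    segIds <- rep(seq_along(segLens), segLens)[seq_len(n)]
    words <- data.frame(
      segment = segIds,
      speaker = sprintf("SPEAKER_%02d", (segIds - 1L) %% spec$nSpeakers),
      start_ms = as.integer(starts[seq_len(n)]),
      end_ms = as.integer(ends[seq_len(n)]),
      text = sample(FIXTURE_VOCAB, n, replace = TRUE),
      confidence = round(stats::runif(n, 0.8, 1), 3),
      stringsAsFactors = FALSE)
    plan <- spec$phiPlan
    if (is.null(plan)) {
      pos <- if (n >= 8L) seq(6L, n - 2L, by = 12L) else integer(0)
      cats <- rep(names(FIXTURE_SURFACES), length.out = length(pos))
      plan <- data.frame(
        position = pos, category = cats,
        surface = vapply(seq_along(pos), function(k) {
          s <- FIXTURE_SURFACES[[cats[k]]]
          s[1L + (k - 1L) %% length(s)]
        }, ""), stringsAsFactors = FALSE)
    }
    if (any(plan$position < 1 | plan$position > n))
      stop(sprintf("phi plan position %d outside word count %d",
                   plan$position[which(plan$position < 1 |
                                         plan$position > n)[1]], n),
           call. = FALSE)
    words$text[plan$position] <- plan$surface
    spans <- data.frame(word_start_index = as.integer(plan$position),
                        word_end_index = as.integer(plan$position),
                        category = as.character(plan$category),
                        matched_text = as.character(plan$surface),
                        rule_id = rep("planted", nrow(plan)),
                        stringsAsFactors = FALSE)
    spans <- spans[order(spans$word_start_index), ]
    rownames(spans) <- NULL
    list(transcript = transcriptFromWords(words, durationMs = durationMs),
         spans = spans, plan = plan)
  })
}

#' Rule set matched to a fixture's planted PHI
#'
#' Builds a [redactionRules()] whose lexicons contain exactly the planted
#' name/location surfaces (pattern categories are covered by
#' [defaultPhiPatterns()]), closing the loop between generator and
#' detector.
#'
#' @param plan phi plan from [genTranscript()]
#' @export
fixtureRedactionRules <- function(plan) {
  redactionRules(
    nameLexicon = plan$surface[plan$category == "NAME"],
    locationLexicon = plan$surface[plan$category == "LOCATION"])
}

#' Generate voice-like audio matching a transcript
#'
#' Each word interval carries a harmonic "vowel" at the speaker's
#' fundamental frequency (8 harmonics, 1/k amplitude roll-off, 10 ms
#' onset/offset ramps) over a seeded low-level noise floor. The default
#' speaker F0s keep all harmonics outside the default 440 Hz tone band, so
#' scrubbed and unscrubbed intervals are spectrally distinguishable.
#'
#' @param spec a [fixtureSpec()]
#' @param transcript the [Transcript-class] from [genTranscript()]
#' @return an [AudioBuffer-class] of duration `spec$durationS`
#' @export
genAudio <- function(spec, transcript) {
  stopifnot(inherits(spec, "fixtureSpec"))
  sr <- spec$sampleRateHz
  L <- roundHalfUp(spec$durationS * sr)
  withSeed(spec$seed + 1000L, {
    x <- stats::rnorm(L, 0, 0.002)
    w <- transcriptWords(transcript)
    speakers <- sort(unique(w$speaker))
    for (wi in seq_len(nrow(w))) {
      f0 <- spec$f0PerSpeaker[match(w$speaker[wi], speakers)]
      n0 <- roundHalfUp(w$start_ms[wi] * sr / 1000)
      n1 <- min(roundHalfUp(w$end_ms[wi] * sr / 1000), L)
      if (n1 <= n0) next
      n <- n0:(n1 - 1L)
      tt <- n / sr
      s <- numeric(length(n))
      for (k in 1:8) {
        fk <- k * f0
        if (fk >= sr / 2) break
        s <- s + (1 / k) * sin(2 * pi * fk * tt)
      }
      s <- 0.35 * s / max(abs(s))
      nf <- roundHalfUp(0.010 * sr)
      kk <- seq_along(n)
      s <- s * pmin(1, kk / nf, (length(n) - kk + 1) / nf)
      x[n + 1L] <- x[n + 1L] + s
    }
    audioBuffer(clampNum(x, -1, 1), sr)
  })
}

# 17-point stick-figure template, in units of person height, y down,
# origin at mid-hip.
personTemplate <- function() {
  m <- matrix(c(
     0.00, -0.50,   # nose
    -0.05, -0.56,  0.05, -0.56,   # eyes
    -0.09, -0.53,  0.09, -0.53,   # ears
    -0.12, -0.38,  0.12, -0.38,   # shoulders
    -0.16, -0.20,  0.16, -0.20,   # elbows
    -0.17, -0.04,  0.17, -0.04,   # wrists
    -0.08,  0.00,  0.08,  0.00,   # hips
    -0.09,  0.25,  0.09,  0.25,   # knees
    -0.10,  0.48,  0.10,  0.48),  # ankles
    ncol = 2, byrow = TRUE)
  rownames(m) <- cocoKeypointNames()
  m
}

checkerboard <- function(h, w, period = 1L, lo = 0.2, hi = 0.8) {
  rows <- (seq_len(h) - 1L) %/% period
  cols <- (seq_len(w) - 1L) %/% period
  m <- outer(rows, cols, function(r, c) (r + c) %% 2)
  lo + (hi - lo) * m
}

defaultMotionPlan <- function(spec) {
  h <- spec$frameSize[1]; w <- spec$frameSize[2]; nF <- spec$nFrames
  lapply(seq_len(spec$nPersons), function(p) {
    if (p %% 2 == 1)
      rbind(c(0, 0.30 * w, 0.55 * h), c(nF - 1, 0.65 * w, 0.50 * h))
    else
      rbind(c(0, 0.72 * w, 0.52 * h), c(nF - 1, 0.32 * w, 0.58 * h))
  })
}

#' Generate a stick-figure pose clip with ground truth
#'
#' Figures follow piecewise-linear waypoint trajectories over a
#' high-variance checkerboard background. Rendered frames, jittered
#' detections with seeded dropout runs (never at the first or last frame,
#' so every track has anchoring observations), and the exact ground-truth
#' keypoint tracks are all returned.
#'
#' @param spec a [fixtureSpec()]
#' @param motionPlan list (per person) of waypoint matrices with rows
#'   (frame, center_x, center_y); default: horizontal crossings
#' @return list: frames (list of matrices), detections (per-frame list, the
#'   [parseDetections()] structure), truth (per-person list of
#'   `[nFrames, 17, 2]` arrays), truthConf, droppedFrames (per person)
#' @export
genPoseClip <- function(spec, motionPlan = NULL) {
  stopifnot(inherits(spec, "fixtureSpec"))
  h <- spec$frameSize[1]; w <- spec$frameSize[2]
  nF <- spec$nFrames
  if (is.null(motionPlan)) motionPlan <- defaultMotionPlan(spec)
  template <- personTemplate() * spec$personHeightPx
  bg <- checkerboard(h, w)
  withSeed(spec$seed + 2000L, {
    truth <- lapply(seq_len(spec$nPersons), function(p) {
      wp <- motionPlan[[p]]
      cx <- stats::approx(wp[, 1], wp[, 2], xout = 0:(nF - 1), rule = 2)$y
      cy <- stats::approx(wp[, 1], wp[, 3], xout = 0:(nF - 1), rule = 2)$y
      arr <- array(NA_real_, c(nF, 17L, 2L))
      for (f in seq_len(nF)) {
        arr[f, , 1] <- cx[f] + template[, 1]
        arr[f, , 2] <- cy[f] + template[, 2]
      }
      arr
    })
    dropped <- lapply(seq_len(spec$nPersons), function(p) {
      out <- logical(nF)
      f <- 2L
      while (f < nF) {      # frames 1 and nF never drop
        if (stats::runif(1) < spec$dropoutRate) {
          run <- sample.int(spec$dropoutMaxGap, 1)
          out[f:min(f + run - 1L, nF - 1L)] <- TRUE
          f <- f + run
        }
        f <- f + 1L
      }
      out
    })
    detections <- lapply(seq_len(nF), function(f) {
      persons <- list()
      for (p in seq_len(spec$nPersons)) {
        if (dropped[[p]][f]) next
        kp <- cbind(
          truth[[p]][f, , 1] + stats::rnorm(17, 0, spec$jitterSd),
          truth[[p]][f, , 2] + stats::rnorm(17, 0, spec$jitterSd),
          stats::runif(17, 0.55, 0.95))
        colnames(kp) <- c("x", "y", "conf")
        persons[[length(persons) + 1L]] <- kp
      }
      list(frame = f - 1L, persons = persons)
    })
    renderParams <- privacyModeParams(
      "GPP", overlay = list(pointRadius = 2, lineWidth = 2, color = 0.05),
      kpConfThreshold = 0)
    frames <- lapply(seq_len(nF), function(f) {
      persons <- lapply(seq_len(spec$nPersons), function(p)
        cbind(truth[[p]][f, , ], 1))
      fr <- bg
      fr[overlayMask(persons, renderParams, c(h, w))] <- 0.05
      fr
    })
    list(frames = frames, detections = detections, truth = truth,
         droppedFrames = dropped)
  })
}

#' Write a complete fixture set to disk
#'
#' Emits the formats the pipeline consumes: `transcript.json`, `audio.wav`,
#' `frames/` (PNG sequence), `detections.json`, plus `ground_truth.json`
#' (planted spans, dropout masks) and `rules.yaml`.
#'
#' @param spec a [fixtureSpec()]
#' @param dir output directory (created)
#' @return invisibly, the list of generated objects
#' @export
writeFixture <- function(spec, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tr <- genTranscript(spec)
  audio <- genAudio(spec, tr$transcript)
  clip <- genPoseClip(spec)
  serializeTranscript(tr$transcript, file.path(dir, "transcript.json"))
  writeWav(audio, file.path(dir, "audio.wav"))
  writeFrames(clip$frames, file.path(dir, "frames"))
  writeDetections(clip$detections, file.path(dir, "detections.json"))
  rules <- list(
    name_lexicon = as.list(tr$plan$surface[tr$plan$category == "NAME"]),
    location_lexicon = as.list(
      tr$plan$surface[tr$plan$category == "LOCATION"]),
    safe_lexicon = list(),
    placeholder_style = "[{CATEGORY}]")
  yaml::write_yaml(rules, file.path(dir, "rules.yaml"))
  gt <- list(spans = tr$spans, droppedFrames = clip$droppedFrames,
             fps = spec$fps, seed = spec$seed)
  writeLines(jsonlite::toJSON(gt, auto_unbox = TRUE, digits = NA,
                              dataframe = "rows"),
             file.path(dir, "ground_truth.json"))
  invisible(list(transcript = tr, audio = audio, clip = clip))
}
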