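#' Tone specification for PHI replacement
#'
#' A tone (rather than silence) marks scrubbed speech, since silence itself
#' can carry meaning in patient-provider interaction. Defaults: 440 Hz at
#' amplitude 0.2 with 10 ms linear fades, audible without clipping.
#'
#' @param frequencyHz tone frequency; must stay below the Nyquist frequency
#'   of the buffer it is applied to
#' @param amplitude peak amplitude in (0, 1]
#' @param fadeMs linear fade-in/out duration at each interval edge, ms
#' @export
toneSpec <- function(frequencyHz = 440, amplitude = 0.2, fadeMs = 10) {
  stopifnot(frequencyHz > 0, amplitude > 0, amplitude <= 1, fadeMs >= 0)
  structure(list(frequencyHz = frequencyHz, amplitude = amplitude,
                 fadeMs = fadeMs), class = "toneSpec")
}

#' Voice transformation parameters
#'
#' Fixed-ratio mode sets `f0Ratio`/`envelopeWarp` directly; randomized mode
#' ([sampleVoiceParams()]) draws them per speaker from `ratioRanges`,
#' excluding near-identity values so the disguise is never a no-op.
#'
#' @param f0Ratio fundamental-frequency scaling (> 0)
#' @param envelopeWarp spectral-envelope frequency scaling (> 0)
#' @param seed integer seed for randomized draws
#' @param ratioRanges list of low/high pairs the randomized f0 ratio is
#'   drawn from (log-uniformly); default excludes (0.85, 1.2)
#' @param envWarpRange range for the randomized envelope warp
#' @export
voiceTransformParams <- function(f0Ratio = 1, envelopeWarp = 1, seed = 1L,
                                 ratioRanges = list(c(0.7, 0.85),
                                                    c(1.2, 1.45)),
                                 envWarpRange = c(0.9, 1.1)) {
  stopifnot(f0Ratio > 0, envelopeWarp > 0)
  structure(list(f0Ratio = f0Ratio, envelopeWarp = envelopeWarp,
                 seed = as.integer(seed), ratioRanges = ratioRanges,
                 envWarpRange = envWarpRange),
            class = "voiceTransformParams")
}

#' Draw per-speaker voice transformation parameters
#'
#' One draw per speaker label, so a speaker keeps one consistent disguise
#' within a file. The f0 ratio is drawn log-uniformly across the configured
#' ranges (each range weighted by its log-width); the envelope warp is drawn
#' log-uniformly from `envWarpRange`.
#'
#' @param speakers character vector of speaker labels
#' @param seed integer seed (draws are reproducible given the seed and the
#'   sorted speaker set)
#' @param ratioRanges,envWarpRange see [voiceTransformParams()]
#' @return named list of [voiceTransformParams()] per speaker
#' @export
sampleVoiceParams <- function(speakers, seed = 1L,
                              ratioRanges = list(c(0.7, 0.85),
                                                 c(1.2, 1.45)),
                              envWarpRange = c(0.9, 1.1)) {
  speakers <- sort(unique(speakers))
  withSeed(seed, {
    out <- lapply(seq_along(speakers), function(i) {
      lw <- vapply(ratioRanges, function(r) log(r[2]) - log(r[1]), 0)
      ri <- sample.int(length(ratioRanges), 1, prob = lw)
      r <- ratioRanges[[ri]]
      f0 <- exp(stats::runif(1, log(r[1]), log(r[2])))
      ew <- exp(stats::runif(1, log(envWarpRange[1]), log(envWarpRange[2])))
      voiceTransformParams(f0Ratio = f0, envelopeWarp = ew, seed = seed,
                           ratioRanges = ratioRanges,
                           envWarpRange = envWarpRange)
    })
    names(out) <- speakers
    out
  })
}

#' Map PHI spans to millisecond audio intervals
#'
#' Each span becomes `[min start_ms, max end_ms)` over its words; intervals
#' separated by less than `mergeGapMs` are merged (so no audible sliver of
#' speech survives between adjacent PHI words). Output is sorted and
#' pairwise disjoint.
#'
#' @param t a [Transcript-class]
#' @param spans spans from [detectPhi()]
#' @param mergeGapMs gap threshold for merging adjacent intervals
#' @return data.frame: start_ms, end_ms, category (comma-joined when merged
#'   intervals differ), source_word_indices (comma-joined)
#' @export
phiIntervals <- function(t, spans, mergeGapMs = 50) {
  empty <- data.frame(start_ms = integer(), end_ms = integer(),
                      category = character(),
                      source_word_indices = character(),
                      stringsAsFactors = FALSE)
  if (!nrow(spans)) return(empty)
  w <- t@words
  raw <- lapply(seq_len(nrow(spans)), function(si) {
    idx <- spans$word_start_index[si]:spans$word_end_index[si]
    pos <- match(idx, w$index)
    if (anyNA(pos))
      stop(sprintf("span %d references word index %d not present in transcript",
                   si, idx[which(is.na(pos))[1]]), call. = FALSE)
    list(start = min(w$start_ms[pos]), end = max(w$end_ms[pos]),
         category = spans$category[si], words = idx)
  })
  starts <- vapply(raw, `[[`, 0, "start")
  ends <- vapply(raw, `[[`, 0, "end")
  # Half-open [start, end) mapped to closed integer ranges [start, end-1];
  # reduce() merges ranges whose gap is < min.gapwidth.
  ir <- IRanges::IRanges(start = starts, end = pmax(ends - 1L, starts))
  red <- IRanges::reduce(ir, min.gapwidth = max(1L, as.integer(mergeGapMs)),
                         with.revmap = TRUE)
  revmap <- S4Vectors::mcols(red)$revmap
  out <- do.call(rbind, lapply(seq_along(red), function(i) {
    members <- revmap[[i]]
    data.frame(
      start_ms = as.integer(IRanges::start(red)[i]),
      end_ms = as.integer(max(ends[members])),
      category = paste(sort(unique(unlist(
        lapply(raw[members], `[[`, "category")))), collapse = ","),
      source_word_indices = paste(sort(unique(unlist(
        lapply(raw[members], `[[`, "words")))), collapse = ","),
      stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Replace PHI intervals with tones
#'
#' Samples inside each half-open interval `[start_ms, end_ms)` are replaced
#' by a sinusoid at the tone frequency and amplitude, with linear fades at
#' both edges; the sinusoid phase is continuous in absolute time
#' (`sin(2 pi f n / sr)` at absolute sample index n). Samples outside all
#' intervals are bit-identical to the input and the sample count is
#' conserved.
#'
#' @param a an [AudioBuffer-class]
#' @param intervals data.frame with start_ms / end_ms (e.g. from
#'   [phiIntervals()])
#' @param tone a [toneSpec()]
#' @return a new [AudioBuffer-class]
#' @export
insertTones <- function(a, intervals, tone = toneSpec()) {
  stopifnot(is(a, "AudioBuffer"))
  sr <- a@sampleRate
  if (tone$frequencyHz >= sr / 2)
    stop(sprintf("tone frequency %.0f Hz is not below Nyquist (%d Hz)",
                 tone$frequencyHz, sr %/% 2), call. = FALSE)
  x <- a@samples
  L <- length(x)
  durMs <- audioDurationMs(a)
  for (i in seq_len(NROW(intervals))) {
    s <- intervals$start_ms[i]; e <- intervals$end_ms[i]
    if (s < 0 || e > durMs)
      stop(sprintf("interval [%d, %d) ms exceeds buffer duration %d ms",
                   s, e, durMs), call. = FALSE)
    n0 <- roundHalfUp(s * sr / 1000)            # 0-based, half-open
    n1 <- min(roundHalfUp(e * sr / 1000), L)
    if (n1 <= n0) next
    n <- n0:(n1 - 1L)
    toneWave <- tone$amplitude * sin(2 * pi * tone$frequencyHz * n / sr)
    nf <- roundHalfUp(tone$fadeMs * sr / 1000)
    if (nf > 0) {
      k <- seq_along(n)
      env <- pmin(1, k / nf, (length(n) - k + 1) / nf)
      toneWave <- toneWave * env
    }
    x[n + 1L] <- toneWave
  }
  audioBuffer(x, sr)
}

#' Autocorrelation fundamental-frequency track
#'
#' Frame-wise normalized-autocorrelation pitch estimator with parabolic peak
#' interpolation. A frame is voiced when its normalized autocorrelation peak
#' exceeds `voicingThreshold` and its RMS exceeds `energyFloor`.
#'
#' @param a an [AudioBuffer-class]
#' @param frameMs,hopMs analysis frame and hop, ms
#' @param fMin,fMax F0 search range, Hz
#' @param voicingThreshold normalized-ACF peak threshold for voicing
#' @param energyFloor RMS below which a frame is unvoiced
#' @return data.frame: frame, time_ms (frame center), f0_hz (NA when
#'   unvoiced), voiced
#' @export
estimateF0Track <- function(a, frameMs = 40, hopMs = 10, fMin = 60,
                            fMax = 450, voicingThreshold = 0.5,
                            energyFloor = 1e-4) {
  stopifnot(is(a, "AudioBuffer"))
  sr <- a@sampleRate
  x <- a@samples
  n <- max(16L, roundHalfUp(frameMs * sr / 1000))
  hop <- max(1L, roundHalfUp(hopMs * sr / 1000))
  lagMin <- max(2L, floor(sr / fMax))
  lagMax <- min(n - 2L, ceiling(sr / fMin))
  nFrames <- max(0L, 1L + (length(x) - n) %/% hop)
  rows <- vector("list", nFrames)
  for (k in seq_len(nFrames)) {
    i0 <- (k - 1L) * hop
    fr <- x[(i0 + 1L):(i0 + n)]
    fr <- fr - mean(fr)
    rms <- sqrt(mean(fr^2))
    f0 <- NA_real_; voiced <- FALSE
    if (rms >= energyFloor && lagMax > lagMin) {
      m <- 2L^ceiling(log2(2L * n))
      sp <- stats::fft(c(fr, numeric(m - n)))
      ac <- Re(stats::fft(sp * Conj(sp), inverse = TRUE))[1:n] / m
      r <- ac / ac[1]
      seg <- r[(lagMin + 1L):(lagMax + 1L)]
      pk <- which.max(seg)
      lag <- lagMin + pk - 1L
      if (seg[pk] >= voicingThreshold) {
        # parabolic interpolation around the peak for sub-sample lag
        if (lag > lagMin && lag < lagMax) {
          y1 <- r[lag]; y2 <- r[lag + 1L]; y3 <- r[lag + 2L]
          denom <- y1 - 2 * y2 + y3
          delta <- if (abs(denom) > 1e-12) 0.5 * (y1 - y3) / denom else 0
          lag <- lag + clampNum(delta, -0.5, 0.5)
        }
        f0 <- sr / lag
        voiced <- TRUE
      }
    }
    rows[[k]] <- data.frame(frame = k - 1L,
                            time_ms = roundHalfUp((i0 + n / 2) * 1000 / sr),
                            f0_hz = f0, voiced = voiced)
  }
  if (!nFrames)
    return(data.frame(frame = integer(), time_ms = integer(),
                      f0_hz = numeric(), voiced = logical()))
  do.call(rbind, rows)
}

#' Median F0 of the voiced frames
#' @inheritParams estimateF0Track
#' @param ... passed to [estimateF0Track()]
#' @export
medianF0 <- function(a, ...) {
  tr <- estimateF0Track(a, ...)
  stats::median(tr$f0_hz[tr$voiced], na.rm = TRUE)
}

#' Transform a voice to disguise speaker identity
#'
#' Scales the fundamental frequency by `p$f0Ratio` and warps the spectral
#' envelope by `p$envelopeWarp` through the supplied vocoder backend
#' (default: [phaseVocoderBackend()]). The sample count is always conserved
#' (speed is untouched). A silent buffer is returned unchanged with a
#' warning, since there is no fundamental frequency to shift.
#'
#' @param a an [AudioBuffer-class] (mono)
#' @param p a [voiceTransformParams()]
#' @param backend function(samples, sampleRate, f0Ratio, envelopeWarp)
#' @return a new [AudioBuffer-class] of identical length
#' @export
transformVoice <- function(a, p, backend = phaseVocoderBackend) {
  stopifnot(is(a, "AudioBuffer"), inherits(p, "voiceTransformParams"))
  if (!length(a@samples) || all(a@samples == 0)) {
    warning("silent input: no fundamental frequency to transform")
    return(a)
  }
  y <- backend(a@samples, a@sampleRate, p$f0Ratio, p$envelopeWarp)
  if (length(y) != length(a@samples))
    stop("vocoder backend changed the sample count", call. = FALSE)
  peak <- max(abs(y))
  if (peak > 1) y <- y / peak
  audioBuffer(y, a@sampleRate)
}

#' Scrub an audio track: per-speaker voice transformation, then PHI tones
#'
#' The full audio de-identification stage. Each speaker's segments are
#' transformed with that speaker's (fixed or seeded-random) parameters so a
#' speaker keeps one consistent disguise; PHI intervals mapped from the
#' redaction spans are then overwritten with tones. Both steps conserve the
#' sample count, so word timestamps remain valid throughout.
#'
#' @param a an [AudioBuffer-class]
#' @param t the [Transcript-class] the spans refer to
#' @param spans PHI spans from [detectPhi()]
#' @param tone a [toneSpec()]
#' @param voiceParams NULL to disable transformation, a single
#'   [voiceTransformParams()] applied to the whole track ("file" scope), or
#'   a named per-speaker list as from [sampleVoiceParams()]
#' @param mergeGapMs see [phiIntervals()]
#' @param backend vocoder backend, see [transformVoice()]
#' @return list: audio (scrubbed [AudioBuffer-class]), intervals (the PHI
#'   interval table), voiceParams (as applied)
#' @export
scrubAudio <- function(a, t, spans, tone = toneSpec(), voiceParams = NULL,
                       mergeGapMs = 50, backend = phaseVocoderBackend) {
  stopifnot(is(a, "AudioBuffer"), is(t, "Transcript"))
  out <- a
  if (!is.null(voiceParams)) {
    if (inherits(voiceParams, "voiceTransformParams")) {
      out <- transformVoice(out, voiceParams, backend)
    } else {
      sr <- a@sampleRate
      segs <- t@segments
      for (spk in names(voiceParams)) {
        ss <- segs[segs$speaker == spk, , drop = FALSE]
        if (!nrow(ss)) next
        ir <- IRanges::reduce(IRanges::IRanges(
          start = ss$start_ms, end = pmax(ss$end_ms - 1L, ss$start_ms)))
        for (i in seq_along(ir)) {
          n0 <- roundHalfUp(IRanges::start(ir)[i] * sr / 1000)
          n1 <- min(roundHalfUp((IRanges::end(ir)[i] + 1L) * sr / 1000),
                    length(out@samples))
          if (n1 - n0 < 64) next
          piece <- audioBuffer(out@samples[(n0 + 1L):n1], sr)
          piece <- suppressWarnings(
            transformVoice(piece, voiceParams[[spk]], backend))
          out@samples[(n0 + 1L):n1] <- piece@samples
        }
      }
    }
  }
  intervals <- phiIntervals(t, spans, mergeGapMs)
  out <- insertTones(out, intervals, tone)
  list(audio = out, intervals = intervals, voiceParams = voiceParams)
}
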