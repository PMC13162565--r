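#' Stream timing record
#'
#' Processing-induced delay plus the intrinsic rate of one stream, as logged
#' by each stage for the synchronization step.
#' @param stream "audio" or "video"
#' @param intrinsicDelayMs signed processing delay in ms
#' @param fps video frame rate (video streams)
#' @param sampleRateHz audio sampling rate (audio streams)
#' @export
streamTiming <- function(stream = c("audio", "video"), intrinsicDelayMs = 0L,
                         fps = NA_real_, sampleRateHz = NA_integer_) {
  stream <- match.arg(stream)
  structure(list(stream = stream,
                 intrinsicDelayMs = as.integer(intrinsicDelayMs),
                 fps = fps, sampleRateHz = sampleRateHz),
            class = "streamTiming")
}

#' Audio-video offset from the stage-logged delays
#'
#' `offset_ms = audio delay - video delay`: positive when the audio stream
#' lags the video. Offsets come from the ledger of delays each stage
#' recorded, not from signal cross-correlation.
#' @param audioTiming,videoTiming [streamTiming()] records
#' @return signed offset in ms
#' @export
computeOffset <- function(audioTiming, videoTiming) {
  if (is.null(audioTiming) || is.null(videoTiming))
    stop("both stream timing records are required", call. = FALSE)
  stopifnot(audioTiming$stream == "audio", videoTiming$stream == "video")
  audioTiming$intrinsicDelayMs - videoTiming$intrinsicDelayMs
}

#' Align audio to video given a signed offset
#'
#' A positive offset (audio lags) trims the audio start by `offset` ms; a
#' negative offset pads the start with silence. The buffer is then
#' equalized to the target video duration: padded with trailing silence or
#' trimmed per `policy` ("pad" keeps content, extending the shorter stream;
#' "trim" cuts the longer one).
#'
#' @param a an [AudioBuffer-class]
#' @param offsetMs signed offset from [computeOffset()]
#' @param targetMs video duration to equalize toward (NULL: skip)
#' @param policy "pad" or "trim" for the duration equalization
#' @return an [AudioBuffer-class]
#' @export
alignAudio <- function(a, offsetMs, targetMs = NULL,
                       policy = c("pad", "trim")) {
  policy <- match.arg(policy)
  sr <- a@sampleRate
  x <- a@samples
  nOff <- roundHalfUp(abs(offsetMs) * sr / 1000)
  if (offsetMs > 0) x <- if (nOff < length(x)) x[-seq_len(nOff)] else numeric()
  if (offsetMs < 0) x <- c(numeric(nOff), x)
  if (!is.null(targetMs)) {
    nTarget <- roundHalfUp(targetMs * sr / 1000)
    if (length(x) < nTarget) {
      if (policy == "pad") x <- c(x, numeric(nTarget - length(x)))
    } else if (length(x) > nTarget) {
      x <- x[seq_len(nTarget)]
    }
  }
  audioBuffer(x, sr)
}

writeU32 <- function(con, v) writeBin(as.integer(v), con, 4,
                                      endian = "little")
writeU16 <- function(con, v) writeBin(as.integer(v), con, 2,
                                      endian = "little")
writeTag <- function(con, tag) writeChar(tag, con, eos = NULL)

frameToBGR <- function(frame) {
  h <- dim(frame)[1]; w <- dim(frame)[2]
  if (length(dim(frame)) == 2) { r <- frame; g <- frame; b <- frame }
  else { r <- frame[, , 1]; g <- frame[, , 2]; b <- frame[, , 3] }
  q <- function(m) {
    m <- round(clampNum(m, 0, 1) * 255)
    storage.mode(m) <- "integer"
    m
  }
  rowPad <- (4 - (w * 3) %% 4) %% 4
  out <- raw((w * 3 + rowPad) * h)
  pos <- 0L
  bI <- q(b); gI <- q(g); rI <- q(r)
  for (row in h:1) {                     # DIB rows are bottom-up
    px <- rbind(bI[row, ], gI[row, ], rI[row, ])
    chunk <- as.raw(as.vector(px))
    out[(pos + 1L):(pos + length(chunk))] <- chunk
    pos <- pos + length(chunk) + rowPad
  }
  out
}

#' Multiplex frames and audio into an uncompressed AVI container
#'
#' The built-in lossless profile: 24-bit uncompressed DIB video plus 16-bit
#' PCM audio in a RIFF/AVI container, written in pure R with no external
#' binary and no embedded timestamps, so output files are bit-stable and
#' probe checks are exact. The source frame rate and audio sampling rate
#' are written unchanged.
#'
#' @param frames list of frames (matrices or RGB arrays in [0, 1])
#' @param audio an [AudioBuffer-class]
#' @param fps video frame rate
#' @param path output .avi path
#' @return `path`, invisibly
#' @export
writeAvi <- function(frames, audio, fps, path) {
  stopifnot(length(frames) > 0)
  if (!length(audio@samples)) stop("audio stream is empty", call. = FALSE)
  h <- dim(frames[[1]])[1]; w <- dim(frames[[1]])[2]
  rowPad <- (4 - (w * 3) %% 4) %% 4
  frameBytes <- (w * 3 + rowPad) * h
  nFrames <- length(frames)
  sr <- audio@sampleRate
  pcm <- as.integer(round(clampNum(audio@samples, -1, 1) * 32767))
  audioBytes <- 2L * length(pcm)

  # RIFF size arithmetic: a chunk is 8 + payload on disk; a LIST's size
  # field counts its 4-byte type plus payload.
  strlVideoPayload <- (8L + 56L) + (8L + 40L)
  strlAudioPayload <- (8L + 56L) + (8L + 16L)
  hdrlPayload <- (8L + 56L) + (12L + strlVideoPayload) +
    (12L + strlAudioPayload)
  moviPayload <- nFrames * (8L + frameBytes) + 8L + audioBytes
  riffSize <- 4L + (12L + hdrlPayload) + (12L + moviPayload)

  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  writeTag(con, "RIFF"); writeU32(con, riffSize); writeTag(con, "AVI ")
  writeTag(con, "LIST"); writeU32(con, 4L + hdrlPayload)
  writeTag(con, "hdrl")
  # main header
  writeTag(con, "avih"); writeU32(con, 56)
  writeU32(con, round(1e6 / fps))                  # us per frame
  writeU32(con, frameBytes * ceiling(fps) + sr * 2); writeU32(con, 0)
  writeU32(con, 0)                                 # flags
  writeU32(con, nFrames); writeU32(con, 0); writeU32(con, 2)
  writeU32(con, frameBytes); writeU32(con, w); writeU32(con, h)
  for (i in 1:4) writeU32(con, 0)
  # video stream
  writeTag(con, "LIST"); writeU32(con, 4L + strlVideoPayload)
  writeTag(con, "strl")
  writeTag(con, "strh"); writeU32(con, 56)
  writeTag(con, "vids"); writeTag(con, "DIB ")
  writeU32(con, 0); writeU16(con, 0); writeU16(con, 0); writeU32(con, 0)
  writeU32(con, 1000L)                             # dwScale
  writeU32(con, round(fps * 1000))                 # dwRate (fps = rate/scale)
  writeU32(con, 0); writeU32(con, nFrames); writeU32(con, frameBytes)
  writeU32(con, -1); writeU32(con, 0)
  writeU16(con, 0); writeU16(con, 0); writeU16(con, w); writeU16(con, h)
  writeTag(con, "strf"); writeU32(con, 40)
  writeU32(con, 40); writeU32(con, w); writeU32(con, h)
  writeU16(con, 1); writeU16(con, 24); writeU32(con, 0)
  writeU32(con, frameBytes); writeU32(con, 0); writeU32(con, 0)
  writeU32(con, 0); writeU32(con, 0)
  # audio stream
  writeTag(con, "LIST"); writeU32(con, 4L + strlAudioPayload)
  writeTag(con, "strl")
  writeTag(con, "strh"); writeU32(con, 56)
  writeTag(con, "auds"); writeU32(con, 0)
  writeU32(con, 0); writeU16(con, 0); writeU16(con, 0); writeU32(con, 0)
  writeU32(con, 1L)                                # dwScale
  writeU32(con, sr)                                # dwRate (samples/s)
  writeU32(con, 0); writeU32(con, length(pcm)); writeU32(con, audioBytes)
  writeU32(con, -1); writeU32(con, 2L)             # sample size 2 bytes
  writeU16(con, 0); writeU16(con, 0); writeU16(con, 0); writeU16(con, 0)
  writeTag(con, "strf"); writeU32(con, 16)
  writeU16(con, 1); writeU16(con, 1)               # PCM, mono
  writeU32(con, sr); writeU32(con, sr * 2L)
  writeU16(con, 2); writeU16(con, 16)
  # movi
  writeTag(con, "LIST"); writeU32(con, 4L + moviPayload)
  writeTag(con, "movi")
  for (fr in frames) {
    writeTag(con, "00db"); writeU32(con, frameBytes)
    writeBin(frameToBGR(fr), con)
  }
  writeTag(con, "01wb"); writeU32(con, audioBytes)
  writeBin(pcm, con, 2, endian = "little")
  invisible(path)
}

#' Probe an AVI container for stream parameters
#'
#' Reads the stream headers back out of a [writeAvi()]-style container.
#' @param path .avi file
#' @return list: fps, nFrames, sampleRateHz, nSamples, videoDurationMs,
#'   audioDurationMs, width, height
#' @export
probeAvi <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  r32 <- function() readBin(con, "integer", 1, 4, endian = "little")
  if (!identical(readChar(con, 4, useBytes = TRUE), "RIFF"))
    stop("not a RIFF file: ", path, call. = FALSE)
  r32()
  if (!identical(readChar(con, 4, useBytes = TRUE), "AVI "))
    stop("not an AVI file: ", path, call. = FALSE)
  out <- list(); width <- NA; height <- NA
  parseStrh <- function(raw) {
    typ <- rawToChar(raw[1:4])
    scale <- readBin(raw[21:24], "integer", 1, 4, endian = "little")
    rate <- readBin(raw[25:28], "integer", 1, 4, endian = "little")
    len <- readBin(raw[33:36], "integer", 1, 4, endian = "little")
    list(type = typ, scale = scale, rate = rate, length = len)
  }
  walk <- function(end) {
    while (seek(con, where = NA) < end) {
      id <- readChar(con, 4, useBytes = TRUE)
      sz <- r32()
      here <- seek(con, where = NA)
      if (id == "LIST") {
        readChar(con, 4, useBytes = TRUE)
        walk(here + sz)
      } else if (id == "strh") {
        s <- parseStrh(readBin(con, "raw", sz))
        if (s$type == "vids") {
          out$fps <<- s$rate / s$scale
          out$nFrames <<- s$length
        } else if (s$type == "auds") {
          out$sampleRateHz <<- as.integer(s$rate / s$scale)
          out$nSamples <<- s$length
        }
      } else if (id == "strf" && sz == 40) {
        raw <- readBin(con, "raw", sz)
        width <<- readBin(raw[5:8], "integer", 1, 4, endian = "little")
        height <<- readBin(raw[9:12], "integer", 1, 4, endian = "little")
      } else {
        seek(con, where = here + sz + (sz %% 2))
      }
      if (seek(con, where = NA) < here + sz + (sz %% 2))
        seek(con, where = here + sz + (sz %% 2))
    }
  }
  fileEnd <- file.size(path)
  walk(fileEnd)
  out$width <- width; out$height <- height
  out$videoDurationMs <- 1000 * out$nFrames / out$fps
  out$audioDurationMs <- 1000 * out$nSamples / out$sampleRateHz
  out
}

#' Synchronize and multiplex processed audio and video
#'
#' Applies the ledger-derived offset to the audio ([alignAudio()]),
#' equalizes durations, muxes ([writeAvi()] by default, or an external
#' muxer function), and verifies via [probeAvi()] that the frame rate and
#' sampling rate are preserved and that the residual duration difference is
#' at most one video frame period.
#'
#' @param frames list of processed frames
#' @param audio processed [AudioBuffer-class]
#' @param fps source frame rate (preserved in the container)
#' @param path output container path
#' @param offsetMs signed audio-video offset (see [computeOffset()])
#' @param policy duration equalization policy, see [alignAudio()]
#' @param muxer NULL for the built-in AVI writer, or a function
#'   `(frames, audio, fps, path)`
#' @return list: path, probe (the [probeAvi()] result), offsetMs
#' @export
muxAV <- function(frames, audio, fps, path, offsetMs = 0,
                  policy = c("pad", "trim"), muxer = NULL) {
  policy <- match.arg(policy)
  if (!length(audio@samples))
    stop("audio stream is empty; refusing to mux", call. = FALSE)
  if (!length(frames)) stop("video stream is empty", call. = FALSE)
  videoMs <- 1000 * length(frames) / fps
  aligned <- alignAudio(audio, offsetMs, targetMs = videoMs, policy = policy)
  if (policy == "trim") {
    # trimming may leave video longer than audio; drop surplus frames
    nKeep <- min(length(frames),
                 floor(length(aligned@samples) / aligned@sampleRate * fps))
    frames <- frames[seq_len(max(1L, nKeep))]
  }
  if (is.null(muxer)) writeAvi(frames, aligned, fps, path)
  else muxer(frames, aligned, fps, path)
  probe <- probeAvi(path)
  framePeriodMs <- 1000 / fps
  delta <- abs(probe$videoDurationMs - probe$audioDurationMs)
  if (delta > framePeriodMs + 1e-6)
    stop(sprintf("AV duration mismatch %.2f ms exceeds one frame period",
                 delta), call. = FALSE)
  list(path = path, probe = probe, offsetMs = offsetMs)
}
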