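# Minimal RIFF/WAVE reader and writer for mono PCM-16 and IEEE float32,
# the two profiles the pipeline uses end-to-end.

#' Construct an AudioBuffer
#' @param samples numeric vector in [-1, 1]
#' @param sampleRate sampling rate in Hz
#' @export
audioBuffer <- function(samples, sampleRate) {
  new("AudioBuffer", samples = as.numeric(samples),
      sampleRate = as.integer(sampleRate))
}

#' Read a mono WAV file
#'
#' Supports uncompressed PCM 16-bit and IEEE float 32-bit, single channel.
#' Unknown RIFF chunks are skipped.
#' @param path WAV file
#' @return an [AudioBuffer-class]
#' @export
readWav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  tag <- readChar(con, 4, useBytes = TRUE)
  if (!identical(tag, "RIFF")) stop("not a RIFF file: ", path, call. = FALSE)
  readBin(con, "integer", 1, 4, endian = "little")
  if (!identical(readChar(con, 4, useBytes = TRUE), "WAVE"))
    stop("not a WAVE file: ", path, call. = FALSE)
  fmt <- NULL; samples <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    sz <- readBin(con, "integer", 1, 4, endian = "little")
    if (id == "fmt ") {
      raw <- readBin(con, "raw", sz)
      fmt <- list(
        audioFormat = readBin(raw[1:2], "integer", 1, 2, endian = "little"),
        channels = readBin(raw[3:4], "integer", 1, 2, endian = "little"),
        sampleRate = readBin(raw[5:8], "integer", 1, 4, endian = "little"),
        bits = readBin(raw[15:16], "integer", 1, 2, endian = "little"))
    } else if (id == "data") {
      if (is.null(fmt)) stop("malformed WAV: data before fmt", call. = FALSE)
      if (fmt$channels != 1)
        stop("only mono WAV is supported (got ", fmt$channels, " channels)",
             call. = FALSE)
      if (fmt$audioFormat == 1 && fmt$bits == 16) {
        s <- readBin(con, "integer", sz / 2, 2, signed = TRUE,
                     endian = "little")
        samples <- s / 32768
      } else if (fmt$audioFormat == 3 && fmt$bits == 32) {
        samples <- readBin(con, "double", sz / 4, 4, endian = "little")
      } else {
        stop(sprintf("unsupported WAV format (tag %d, %d bits)",
                     fmt$audioFormat, fmt$bits), call. = FALSE)
      }
    } else {
      readBin(con, "raw", sz + (sz %% 2))  # skip (chunks are word-aligned)
    }
    if (!is.null(samples)) break
  }
  if (is.null(samples)) stop("WAV file has no data chunk: ", path,
                             call. = FALSE)
  audioBuffer(clampNum(samples, -1, 1), fmt$sampleRate)
}

#' Write a mono WAV file
#'
#' @param a an [AudioBuffer-class]
#' @param path output file
#' @param format "pcm16" (default) or "float32"
#' @export
writeWav <- function(a, path, format = c("pcm16", "float32")) {
  format <- match.arg(format)
  stopifnot(is(a, "AudioBuffer"))
  x <- clampNum(a@samples, -1, 1)
  sr <- a@sampleRate
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  if (format == "pcm16") {
    bytesPerSample <- 2L; fmtTag <- 1L; bits <- 16L
  } else {
    bytesPerSample <- 4L; fmtTag <- 3L; bits <- 32L
  }
  dataSize <- length(x) * bytesPerSample
  w32 <- function(v) writeBin(as.integer(v), con, 4, endian = "little")
  w16 <- function(v) writeBin(as.integer(v), con, 2, endian = "little")
  writeChar("RIFF", con, eos = NULL); w32(36 + dataSize)
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL); w32(16)
  w16(fmtTag); w16(1); w32(sr); w32(sr * bytesPerSample)
  w16(bytesPerSample); w16(bits)
  writeChar("data", con, eos = NULL); w32(dataSize)
  if (format == "pcm16") {
    writeBin(as.integer(round(x * 32767)), con, 2, endian = "little")
  } else {
    writeBin(as.numeric(x), con, 4, endian = "little")
  }
  invisible(path)
}
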