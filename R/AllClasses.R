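#' @import methods
NULL

WORD_COLUMNS <- c("index", "segment", "speaker", "start_ms", "end_ms",
                  "text", "confidence")
SEGMENT_COLUMNS <- c("segment", "speaker", "start_ms", "end_ms", "text")

KEYPOINT_STATUS <- c("observed", "interpolated", "predicted", "missing")

#' COCO keypoint names, in order
#'
#' The 17-point human pose convention: 5 facial landmarks (nose, eyes, ears)
#' followed by 12 body joints.
#' @export
cocoKeypointNames <- function() {
  c("nose", "left_eye", "right_eye", "left_ear", "right_ear",
    "left_shoulder", "right_shoulder", "left_elbow", "right_elbow",
    "left_wrist", "right_wrist", "left_hip", "right_hip",
    "left_knee", "right_knee", "left_ankle", "right_ankle")
}

#' Indices of the facial keypoints (nose, eyes, ears)
#' @export
cocoFacialIndices <- function() 1:5

#' COCO limb connectivity for skeleton overlays
#'
#' Pairs of keypoint indices (1-based, [cocoKeypointNames()] order) joined by
#' line segments when both endpoints are confidently detected.
#' @return two-column integer matrix of endpoint indices
#' @export
cocoSkeletonEdges <- function() {
  m <- matrix(c(16,14, 14,12, 17,15, 15,13, 12,13, 6,12, 7,13, 6,7,
                6,8, 7,9, 8,10, 9,11, 2,3, 1,2, 1,3, 2,4, 3,5, 4,6, 5,7),
              ncol = 2, byrow = TRUE)
  storage.mode(m) <- "integer"
  m
}

emptyWordTable <- function() {
  data.frame(index = integer(), segment = integer(), speaker = character(),
             start_ms = integer(), end_ms = integer(), text = character(),
             confidence = numeric(), stringsAsFactors = FALSE)
}

emptySegmentTable <- function() {
  data.frame(segment = integer(), speaker = character(),
             start_ms = integer(), end_ms = integer(), text = character(),
             stringsAsFactors = FALSE)
}

#' Diarized transcript with word-level timestamps
#'
#' The spine linking text redaction to audio time: an ordered word table
#' (global 1-based index, speaker, integer-millisecond start/end, text,
#' confidence) plus a segment table and document metadata. Word intervals are
#' half-open `[start_ms, end_ms)`.
#'
#' @slot words data.frame, one row per word in global order
#' @slot segments data.frame, one row per segment
#' @slot language language tag of the transcript
#' @slot durationMs duration of the source audio in milliseconds
#' @export
setClass("Transcript",
  representation(words = "data.frame", segments = "data.frame",
                 language = "character", durationMs = "integer"),
  prototype(words = emptyWordTable(), segments = emptySegmentTable(),
            language = "en", durationMs = 0L))

setValidity("Transcript", function(object) {
  w <- object@words
  s <- object@segments
  if (!all(WORD_COLUMNS %in% names(w)))
    return(paste("words table must have columns:",
                 paste(WORD_COLUMNS, collapse = ", ")))
  if (!all(SEGMENT_COLUMNS %in% names(s)))
    return(paste("segments table must have columns:",
                 paste(SEGMENT_COLUMNS, collapse = ", ")))
  n <- nrow(w)
  if (n > 0) {
    bad <- which(w$end_ms < w$start_ms)
    if (length(bad))
      return(sprintf("word %d ('%s') has end_ms < start_ms",
                     w$index[bad[1]], w$text[bad[1]]))
    if (any(w$start_ms < 0))
      return(sprintf("word %d has negative start_ms",
                     w$index[which(w$start_ms < 0)[1]]))
    if (!identical(w$index, seq_len(n)))
      return("word indices must be 1..n in row order")
    if (is.unsorted(order(w$start_ms, w$index)) ||
        !identical(order(w$start_ms, w$index), seq_len(n)))
      return("words must be sorted by start_ms (ties by index)")
    if (any(w$confidence < 0 | w$confidence > 1))
      return("word confidence must lie in [0, 1]")
    for (g in unique(w$segment)) {
      ws <- w[w$segment == g, ]
      seg <- s[s$segment == g, ]
      if (nrow(seg) != 1)
        return(sprintf("segment id %s missing from segment table", g))
      if (seg$start_ms > min(ws$start_ms) || seg$end_ms < max(ws$end_ms))
        return(sprintf("segment %s does not cover its words' intervals", g))
    }
  }
  if (length(object@durationMs) != 1 || is.na(object@durationMs) ||
      object@durationMs < 0)
    return("durationMs must be a single non-negative integer")
  TRUE
})

#' Mono audio buffer
#'
#' Samples in `[-1, 1]` plus an integer sample rate. Every scrubbing
#' operation conserves the sample count exactly.
#'
#' @slot samples numeric vector of samples
#' @slot sampleRate sampling rate in Hz
#' @export
setClass("AudioBuffer",
  representation(samples = "numeric", sampleRate = "integer"),
  prototype(samples = numeric(), sampleRate = 16000L))

setValidity("AudioBuffer", function(object) {
  if (length(object@sampleRate) != 1 || object@sampleRate <= 0)
    return("sampleRate must be a single positive integer")
  if (length(object@samples) && !all(is.finite(object@samples)))
    return("samples must be finite")
  if (length(object@samples) && max(abs(object@samples)) > 1 + 1e-9)
    return("samples must lie in [-1, 1]")
  TRUE
})

#' One person's keypoint time series
#'
#' Per-frame 17-keypoint coordinates with confidence and a provenance status
#' per keypoint: observed (detector output), interpolated (gap fill),
#' predicted (Kalman prediction without a measurement), or missing.
#'
#' @slot trackId integer track identifier
#' @slot frameIndex sorted integer vector of 0-based frame indices
#' @slot coords numeric array `[n_frames, 17, 2]` of (x, y) pixel coordinates
#' @slot conf numeric matrix `[n_frames, 17]` of confidences
#' @slot status character matrix `[n_frames, 17]`
#' @export
setClass("KeypointTrack",
  representation(trackId = "integer", frameIndex = "integer",
                 coords = "array", conf = "matrix", status = "matrix"))

setValidity("KeypointTrack", function(object) {
  n <- length(object@frameIndex)
  if (n && (is.unsorted(object@frameIndex, strictly = TRUE)))
    return("frameIndex must be strictly increasing")
  if (!identical(dim(object@coords), c(n, 17L, 2L)) &&
      !(n == 0 && length(object@coords) == 0))
    return("coords must be an [n, 17, 2] array")
  if (n && !identical(dim(object@conf), c(n, 17L)))
    return("conf must be an [n, 17] matrix")
  if (n && !identical(dim(object@status), c(n, 17L)))
    return("status must be an [n, 17] matrix")
  if (n && !all(object@status %in% KEYPOINT_STATUS))
    return(paste("status entries must be one of:",
                 paste(KEYPOINT_STATUS, collapse = ", ")))
  TRUE
})

#' Quality-control report
#'
#' @slot mode privacy mode the media were produced under ("PPP" or "GPP")
#' @slot findings data.frame of findings (modality, location, rule_id,
#'   severity, description)
#' @slot status "pass" iff no finding has severity "fail"
#' @slot checklist the mode-specific reviewer checklist
#' @export
setClass("QCReport",
  representation(mode = "character", findings = "data.frame",
                 status = "character", checklist = "data.frame"))

setValidity("QCReport", function(object) {
  wantPass <- !any(object@findings$severity == "fail")
  if ((object@status == "pass") != wantPass)
    return("status must be 'pass' iff no finding has severity 'fail'")
  if (!object@mode %in% c("PPP", "GPP"))
    return("mode must be 'PPP' or 'GPP'")
  TRUE
})

#' @describeIn Transcript-class number of words
#' @param x a Transcript
#' @export
nWords <- function(x) nrow(x@words)

#' @describeIn Transcript-class number of segments
#' @export
nSegments <- function(x) nrow(x@segments)

#' @describeIn Transcript-class word table accessor
#' @export
transcriptWords <- function(x) x@words

#' @describeIn Transcript-class segment table accessor
#' @export
transcriptSegments <- function(x) x@segments

#' @describeIn AudioBuffer-class sample vector accessor
#' @param x an AudioBuffer
#' @export
audioSamples <- function(x) x@samples

#' @describeIn AudioBuffer-class sample rate accessor
#' @export
sampleRate <- function(x) x@sampleRate

#' @describeIn AudioBuffer-class duration in (rounded) milliseconds
#' @export
audioDurationMs <- function(x) roundHalfUp(1000 * length(x@samples) / x@sampleRate)

#' @describeIn KeypointTrack-class track id accessor
#' @param x a KeypointTrack
#' @export
trackId <- function(x) x@trackId

#' @describeIn KeypointTrack-class frame index accessor
#' @export
trackFrames <- function(x) x@frameIndex

#' @describeIn KeypointTrack-class coordinates at one frame
#' @param frame 0-based frame index
#' @export
trackCoords <- function(x, frame = NULL) {
  if (is.null(frame)) return(x@coords)
  i <- match(frame, x@frameIndex)
  if (is.na(i)) return(NULL)
  x@coords[i, , , drop = TRUE]
}

#' @describeIn QCReport-class overall pass/fail status
#' @param x a QCReport
#' @export
qcStatus <- function(x) x@status

#' @describeIn QCReport-class findings table
#' @export
qcFindings <- function(x) x@findings

setMethod("show", "Transcript", function(object) {
  cat(sprintf("Transcript: %d segment(s), %d word(s), %d speaker(s), %d ms\n",
              nSegments(object), nWords(object),
              length(unique(object@words$speaker)), object@durationMs))
})

setMethod("show", "AudioBuffer", function(object) {
  cat(sprintf("AudioBuffer: %d samples @ %d Hz (%.2f s)\n",
              length(object@samples), object@sampleRate,
              length(object@samples) / object@sampleRate))
})

setMethod("show", "KeypointTrack", function(object) {
  n <- length(object@frameIndex)
  cat(sprintf("KeypointTrack %d: %d frame(s)%s\n", object@trackId, n,
              if (n) sprintf(" [%d..%d]", min(object@frameIndex),
                             max(object@frameIndex)) else ""))
})

setMethod("show", "QCReport", function(object) {
  cat(sprintf("QCReport (%s): %s, %d finding(s) (%d fail, %d warn)\n",
              object@mode, toupper(object@status), nrow(object@findings),
              sum(object@findings$severity == "fail"),
              sum(object@findings$severity == "warn")))
})
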