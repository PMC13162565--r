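#' Mode-specific reviewer checklist
#'
#' Four video criteria per privacy mode plus the two audio criteria shared
#' by both modes, each with a stable rule id reusable in findings.
#'
#' @param mode "PPP" or "GPP"
#' @return data.frame: rule_id, modality, description
#' @export
buildChecklist <- function(mode) {
  if (!mode %in% c("PPP", "GPP"))
    stop("unknown privacy mode: ", mode, call. = FALSE)
  video <- if (mode == "PPP") data.frame(
    rule_id = c("ppp.face_obscured", "ppp.tracking", "ppp.context_intact",
                "ppp.no_outside_identifiers"),
    modality = "video",
    description = c(
      "Bounding-box blur fully obscures all facial features",
      "Blur regions follow faces through movement and occlusions",
      "Environmental context outside the blur regions is visible and unaltered",
      "No identifying features are visible outside the blurred regions"),
    stringsAsFactors = FALSE)
  else data.frame(
    rule_id = c("gpp.uniform_blur", "gpp.skeleton_visible",
                "gpp.environment_hidden", "gpp.overlay_nonidentifying"),
    modality = "video",
    description = c(
      "The whole frame carries a consistent blur level",
      "Skeleton keypoints are visible and follow human movement accurately",
      "No environmental detail or identifying information is discernible through the blur",
      "The keypoint overlay itself reveals no facial or other identifying features"),
    stringsAsFactors = FALSE)
  audio <- data.frame(
    rule_id = c("audio.phi_tones", "audio.voice_transform"),
    modality = "audio",
    description = c(
      "Every PHI interval has been replaced with a tone",
      "Voice transformation prevents speaker identification"),
    stringsAsFactors = FALSE)
  rbind(video, audio)
}

qcFinding <- function(modality, location, rule_id, severity, description) {
  data.frame(modality = modality, location = as.character(location),
             rule_id = rule_id, severity = severity,
             description = description, stringsAsFactors = FALSE)
}

emptyFindings <- function() {
  data.frame(modality = character(), location = character(),
             rule_id = character(), severity = character(),
             description = character(), stringsAsFactors = FALSE)
}

#' Scan de-identified frames for residual faces
#'
#' Harness for an adversarial re-detection pass: any face or facial-keypoint
#' detection in output frames marks a frame that needs further attention.
#' The detector is pluggable — `function(frame, frameIndex)` returning a
#' list/data.frame of detections (empty when clean) — since no bundled model
#' is assumed. A detector error on a frame produces a warn finding and the
#' scan continues.
#'
#' @param frames list of de-identified frames
#' @param detector detection function
#' @return list: flaggedFrames (sorted unique 0-based indices), findings
#'   (data.frame), detections (per-frame raw detector output)
#' @export
residualFaceScan <- function(frames, detector) {
  flagged <- integer(); findings <- list(); raw <- vector("list",
                                                          length(frames))
  for (i in seq_along(frames)) {
    res <- tryCatch(detector(frames[[i]], i - 1L), error = function(e) e)
    if (inherits(res, "error")) {
      findings[[length(findings) + 1L]] <- qcFinding(
        "video", i - 1L, "qc.detector_error", "warn",
        paste("detector failed:", conditionMessage(res)))
      next
    }
    raw[[i]] <- res
    if (NROW(res) > 0) {
      flagged <- c(flagged, i - 1L)
      findings[[length(findings) + 1L]] <- qcFinding(
        "video", i - 1L, "qc.residual_face", "fail",
        sprintf("residual face/keypoint detection on frame %d", i - 1L))
    }
  }
  list(flaggedFrames = sort(unique(flagged)),
       findings = if (length(findings)) do.call(rbind, findings)
                  else emptyFindings(),
       detections = raw)
}

#' Per-region blur coverage metric
#'
#' Machine proxy for "adequately obscured": the variance-reduction ratio
#' `1 - var(deid) / var(original)` over the pixels of each region (0 when
#' the original region is constant), plus the exact count of changed pixels
#' outside all regions (which must be 0 for PPP output).
#'
#' @param original,deid frames of identical size
#' @param regions list of face bboxes ([faceBbox()] format)
#' @return list: ratios (numeric per region), outsideChanges (integer)
#' @export
blurCoverageMetric <- function(original, deid, regions) {
  if (!identical(dim(original), dim(deid)))
    stop("frame size mismatch", call. = FALSE)
  fs <- frameSizeOf(original)
  gray <- function(f) if (length(dim(f)) == 3) (f[, , 1] + f[, , 2] +
                                                  f[, , 3]) / 3 else f
  og <- gray(original); dg <- gray(deid)
  inside <- matrix(FALSE, fs[1], fs[2])
  ratios <- vapply(regions, function(bbox) {
    px <- bboxPixels(bbox, fs)
    inside[px$rows, px$cols] <<- TRUE
    vo <- stats::var(as.vector(og[px$rows, px$cols]))
    vd <- stats::var(as.vector(dg[px$rows, px$cols]))
    if (is.na(vo) || vo == 0) 0 else clampNum(1 - vd / vo, 0, 1)
  }, 0)
  outside <- sum((og != dg)[!inside])
  if (length(dim(original)) == 3) {
    for (ch in 1:3)
      outside <- max(outside,
                     sum((original[, , ch] != deid[, , ch])[!inside]))
  }
  list(ratios = ratios, outsideChanges = as.integer(outside))
}

# Fraction of an interval's spectral energy within +- bandWidthHz of the
# tone frequency.
toneBandFraction <- function(x, sr, toneHz, bandWidthHz = 30) {
  n <- length(x)
  if (n < 8) return(0)
  sp <- Mod(stats::fft(x))[1:(n %/% 2)]^2
  freqs <- (seq_along(sp) - 1) * sr / n
  tot <- sum(sp)
  if (tot <= 0) return(0)
  sum(sp[abs(freqs - toneHz) <= bandWidthHz]) / tot
}

#' Scan scrubbed audio for residual speech inside PHI intervals
#'
#' An interval is flagged when its spectrum is not dominated by the
#' configured tone: the fraction of energy within `bandWidthHz` of the tone
#' frequency falls below `threshold`. Ground-truth intervals (fixtures) or
#' re-derived intervals (a re-run ASR backend) can both be supplied.
#'
#' @param a scrubbed [AudioBuffer-class]
#' @param intervals PHI interval table (start_ms / end_ms)
#' @param tone the [toneSpec()] the scrub used
#' @param threshold minimum tone-band energy fraction
#' @param bandWidthHz half-width of the tone band in Hz
#' @return data.frame of flagged intervals with their tone-band fraction
#' @export
residualPhiScan <- function(a, intervals, tone = toneSpec(),
                            threshold = 0.6, bandWidthHz = 30) {
  stopifnot(is(a, "AudioBuffer"))
  sr <- a@sampleRate
  out <- list()
  for (i in seq_len(NROW(intervals))) {
    n0 <- roundHalfUp(intervals$start_ms[i] * sr / 1000)
    n1 <- min(roundHalfUp(intervals$end_ms[i] * sr / 1000),
              length(a@samples))
    if (n1 <= n0) next
    frac <- toneBandFraction(a@samples[(n0 + 1L):n1], sr, tone$frequencyHz,
                             bandWidthHz)
    if (frac < threshold)
      out[[length(out) + 1L]] <- data.frame(
        start_ms = intervals$start_ms[i], end_ms = intervals$end_ms[i],
        tone_band_fraction = frac, stringsAsFactors = FALSE)
  }
  if (length(out)) do.call(rbind, out)
  else data.frame(start_ms = integer(), end_ms = integer(),
                  tone_band_fraction = numeric(), stringsAsFactors = FALSE)
}

#' Check that the voice transformation is not a no-op
#'
#' Compares original and transformed audio: if the voiced median F0 moved
#' by less than `minShiftFrac` and the waveforms are nearly identical
#' (relative RMS difference below `minRmsDiff`), the disguise failed and a
#' fail finding is returned.
#'
#' @param original,transformed [AudioBuffer-class] pair
#' @param excludeIntervals optional interval table (start_ms / end_ms) cut
#'   from both buffers before comparison — pass the PHI intervals so the
#'   inserted tones cannot mask an untransformed voice
#' @param minShiftFrac minimum acceptable relative F0 shift (default 10%)
#' @param minRmsDiff minimum relative RMS waveform difference
#' @return data.frame of findings (possibly empty)
#' @export
qcVoiceTransform <- function(original, transformed, excludeIntervals = NULL,
                             minShiftFrac = 0.1, minRmsDiff = 0.1) {
  if (!is.null(excludeIntervals) && NROW(excludeIntervals)) {
    sr <- original@sampleRate
    keep <- rep(TRUE, length(original@samples))
    for (i in seq_len(NROW(excludeIntervals))) {
      n0 <- roundHalfUp(excludeIntervals$start_ms[i] * sr / 1000)
      n1 <- min(roundHalfUp(excludeIntervals$end_ms[i] * sr / 1000),
                length(keep))
      if (n1 > n0) keep[(n0 + 1L):n1] <- FALSE
    }
    original <- audioBuffer(original@samples[keep], sr)
    transformed <- audioBuffer(transformed@samples[keep],
                               transformed@sampleRate)
  }
  f0a <- medianF0(original); f0b <- medianF0(transformed)
  shift <- if (is.na(f0a) || is.na(f0b) || f0a == 0) 0 else
    abs(f0b - f0a) / f0a
  denom <- sqrt(mean(original@samples^2))
  rmsDiff <- if (denom == 0) Inf else
    sqrt(mean((original@samples - transformed@samples)^2)) / denom
  if (shift < minShiftFrac && rmsDiff < minRmsDiff)
    qcFinding("audio", "track", "audio.voice_transform", "fail",
              sprintf(paste0("voice transformation ineffective: median F0 ",
                             "shifted %.1f%%, relative RMS difference %.3f"),
                      100 * shift, rmsDiff))
  else emptyFindings()
}

#' Compile findings into a QC report
#'
#' @param findings data.frame of findings (may be empty)
#' @param mode privacy mode the media were produced under
#' @return a [QCReport-class]; status is "pass" iff no finding has severity
#'   "fail" (warn-only reports pass, with the warnings listed)
#' @export
compileReport <- function(findings, mode) {
  if (is.null(findings) || !NROW(findings)) findings <- emptyFindings()
  rownames(findings) <- NULL
  status <- if (any(findings$severity == "fail")) "fail" else "pass"
  new("QCReport", mode = mode, findings = findings, status = status,
      checklist = buildChecklist(mode))
}

#' Serialize a QC report to JSON
#' @param report a [QCReport-class]
#' @param path optional output file
#' @export
writeQCReport <- function(report, path = NULL) {
  doc <- list(mode = report@mode, status = report@status,
              findings = report@findings, checklist = report@checklist)
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA,
                           dataframe = "rows", pretty = TRUE)
  if (!is.null(path)) { writeLines(json, path); return(invisible(path)) }
  as.character(json)
}
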