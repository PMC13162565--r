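#' Privacy mode parameters
#'
#' Configuration for the video obscuration stage. PPP (precision mode)
#' blurs face bounding boxes only, preserving environmental context; GPP
#' (greedy mode) blurs the whole frame and overlays the tracked skeleton.
#'
#' Blur sigmas default to geometry-derived values when `NA`: the face-box
#' diagonal / 6 in PPP, the frame diagonal / 100 in GPP.
#'
#' @param mode "PPP" or "GPP"
#' @param blurSigmaFace Gaussian sigma for face regions (NA: bbox diag / 6)
#' @param blurSigmaFrame Gaussian sigma for whole-frame blur (NA: frame
#'   diag / 100)
#' @param bboxMarginFrac face box expansion, as a fraction of the facial
#'   hull diagonal, on every side
#' @param kpConfThreshold keypoint confidence cutoff for face boxes,
#'   overlays and track centroids
#' @param minBoxPx floor edge length (px) for degenerate face boxes whose
#'   facial hull has zero diagonal
#' @param maxGapFrames longest detection gap filled by interpolation
#' @param maxMatchDistPx track association distance gate
#' @param processNoise,measurementNoise Kalman filter noise parameters (px^2)
#' @param overlay skeleton drawing spec: list(pointRadius, lineWidth, color)
#'   with color either a grayscale intensity or an RGB triple in [0, 1]
#' @export
privacyModeParams <- function(mode = c("PPP", "GPP"), blurSigmaFace = NA,
                              blurSigmaFrame = NA, bboxMarginFrac = 0.25,
                              kpConfThreshold = 0.3, minBoxPx = 16,
                              maxGapFrames = 30, maxMatchDistPx = 50,
                              processNoise = 1, measurementNoise = 4,
                              overlay = list(pointRadius = 3, lineWidth = 2,
                                             color = 1)) {
  mode <- match.arg(mode)
  structure(list(mode = mode, blurSigmaFace = blurSigmaFace,
                 blurSigmaFrame = blurSigmaFrame,
                 bboxMarginFrac = bboxMarginFrac,
                 kpConfThreshold = kpConfThreshold, minBoxPx = minBoxPx,
                 maxGapFrames = maxGapFrames,
                 maxMatchDistPx = maxMatchDistPx,
                 processNoise = processNoise,
                 measurementNoise = measurementNoise, overlay = overlay),
            class = "privacyModeParams")
}

frameSizeOf <- function(frame) c(dim(frame)[1], dim(frame)[2])  # (h, w)

#' Gaussian-blur a frame
#'
#' Isotropic Gaussian blur with replicated (clamped) edges; channels of an
#' RGB array are blurred independently.
#' @param frame matrix `[h, w]` or array `[h, w, 3]`, values in [0, 1]
#' @param sigma Gaussian standard deviation in pixels
#' @export
blurFrame <- function(frame, sigma) {
  if (sigma <= 0) return(frame)
  if (length(dim(frame)) == 2)
    return(EBImage::gblur(frame, sigma, boundary = "replicate"))
  out <- frame
  for (ch in seq_len(dim(frame)[3]))
    out[, , ch] <- EBImage::gblur(frame[, , ch], sigma,
                                  boundary = "replicate")
  out
}

#' Face bounding box from facial keypoints
#'
#' The axis-aligned hull of the confident facial keypoints (nose, eyes,
#' ears), expanded by `bboxMarginFrac` of the hull diagonal on every side
#' and clipped to the frame. When the confident points are coincident (zero
#' diagonal) a floor-size box of `minBoxPx` is centered on them. Returns
#' NULL when no facial keypoint reaches the confidence threshold — callers
#' must escalate such frames to QC rather than silently skipping them.
#'
#' @param kps 17x3 matrix of (x, y, conf) in COCO order
#' @param params a [privacyModeParams()]
#' @param frameSize (height, width) in pixels
#' @return named numeric vector (x0, y0, x1, y1) in half-open continuous
#'   pixel coordinates, or NULL
#' @export
faceBbox <- function(kps, params, frameSize) {
  face <- kps[cocoFacialIndices(), , drop = FALSE]
  keep <- face[, 3] >= params$kpConfThreshold
  if (!any(keep)) return(NULL)
  xs <- face[keep, 1]; ys <- face[keep, 2]
  x0 <- min(xs); x1 <- max(xs); y0 <- min(ys); y1 <- max(ys)
  diag <- sqrt((x1 - x0)^2 + (y1 - y0)^2)
  if (diag == 0) {
    half <- params$minBoxPx / 2
    x0 <- x0 - half; x1 <- x1 + half; y0 <- y0 - half; y1 <- y1 + half
  } else {
    m <- params$bboxMarginFrac * diag
    x0 <- x0 - m; x1 <- x1 + m; y0 <- y0 - m; y1 <- y1 + m
  }
  h <- frameSize[1]; w <- frameSize[2]
  out <- c(x0 = max(0, x0), y0 = max(0, y0),
           x1 = min(w, x1), y1 = min(h, y1))
  if (out["x1"] <= out["x0"] || out["y1"] <= out["y0"]) return(NULL)
  out
}

# Integer pixel index ranges (1-based rows/cols) covered by a half-open
# continuous bbox.
bboxPixels <- function(bbox, frameSize) {
  rows <- (floor(bbox["y0"]) + 1L):min(ceiling(bbox["y1"]), frameSize[1])
  cols <- (floor(bbox["x0"]) + 1L):min(ceiling(bbox["x1"]), frameSize[2])
  list(rows = rows, cols = cols)
}

#' Apply precision-mode blurring (PPP)
#'
#' Pixels inside each face region are replaced by the Gaussian-blurred
#' frame; every pixel outside all regions is bit-identical to the input.
#' Each region is blurred on a kernel-padded crop, which equals the
#' full-frame blur on the region interior while keeping the cost
#' proportional to the region size.
#'
#' @param frame matrix or RGB array in [0, 1]
#' @param regions list of bboxes from [faceBbox()] (NULLs are skipped)
#' @param params a [privacyModeParams()]
#' @return the frame with regions blurred
#' @export
applyPPP <- function(frame, regions, params) {
  fs <- frameSizeOf(frame)
  out <- frame
  for (bbox in regions) {
    if (is.null(bbox)) next
    px <- bboxPixels(bbox, fs)
    sigma <- params$blurSigmaFace
    if (is.na(sigma)) {
      d <- sqrt((bbox["x1"] - bbox["x0"])^2 + (bbox["y1"] - bbox["y0"])^2)
      sigma <- max(d / 6, 1)
    }
    pad <- ceiling(3 * sigma) + 1L
    rows <- max(1L, min(px$rows) - pad):min(fs[1], max(px$rows) + pad)
    cols <- max(1L, min(px$cols) - pad):min(fs[2], max(px$cols) + pad)
    crop <- if (length(dim(frame)) == 2) frame[rows, cols, drop = FALSE]
            else frame[rows, cols, , drop = FALSE]
    blurred <- blurFrame(crop, sigma)
    ri <- match(px$rows, rows); ci <- match(px$cols, cols)
    if (length(dim(frame)) == 2) out[px$rows, px$cols] <- blurred[ri, ci]
    else out[px$rows, px$cols, ] <- blurred[ri, ci, ]
  }
  out
}

#' Skeleton overlay mask
#'
#' Logical mask of the pixels covered by the keypoint discs and COCO limb
#' segments for the given persons, at the configured point radius and line
#' width. Only keypoints at or above the confidence threshold are drawn; a
#' limb is drawn only when both endpoints are confident.
#'
#' @param persons list of 17x3 keypoint matrices
#' @param params a [privacyModeParams()]
#' @param frameSize (height, width)
#' @return logical matrix `[h, w]`
#' @export
overlayMask <- function(persons, params, frameSize) {
  h <- frameSize[1]; w <- frameSize[2]
  mask <- matrix(FALSE, h, w)
  r <- params$overlay$pointRadius
  halfW <- params$overlay$lineWidth / 2
  edges <- cocoSkeletonEdges()
  stamp <- function(rows, cols, test) {
    rows <- rows[rows >= 1 & rows <= h]
    cols <- cols[cols >= 1 & cols <= w]
    if (!length(rows) || !length(cols)) return()
    for (rr in rows) for (cc in cols) if (test(cc - 1, rr - 1))
      mask[rr, cc] <<- TRUE
  }
  for (m in persons) {
    confident <- m[, 3] >= params$kpConfThreshold
    for (k in which(confident)) {
      cx <- round(m[k, 1]); cy <- round(m[k, 2])
      stamp((cy - r + 1):(cy + r + 1), (cx - r + 1):(cx + r + 1),
            function(px, py) (px - cx)^2 + (py - cy)^2 <= r^2)
    }
    for (e in seq_len(nrow(edges))) {
      a <- edges[e, 1]; b <- edges[e, 2]
      if (!confident[a] || !confident[b]) next
      p1 <- m[a, 1:2]; p2 <- m[b, 1:2]
      lo <- floor(pmin(p1, p2)) - ceiling(halfW)
      hi <- ceiling(pmax(p1, p2)) + ceiling(halfW)
      v <- p2 - p1; len2 <- sum(v^2)
      stamp((lo[2] + 1):(hi[2] + 1), (lo[1] + 1):(hi[1] + 1),
            function(px, py) {
              tt <- if (len2 == 0) 0 else
                clampNum(((px - p1[1]) * v[1] + (py - p1[2]) * v[2]) / len2,
                         0, 1)
              (px - (p1[1] + tt * v[1]))^2 +
                (py - (p1[2] + tt * v[2]))^2 <= halfW^2
            })
    }
  }
  mask
}

#' Apply greedy-mode obscuration (GPP)
#'
#' Blurs the entire frame, then draws the skeleton overlay (discs at
#' confident keypoints, segments along COCO limb connectivity) in the
#' configured color, preserving scene structure while obscuring all detail.
#'
#' @param frame matrix or RGB array in [0, 1]
#' @param persons list of 17x3 keypoint matrices at this frame
#' @param params a [privacyModeParams()]
#' @return the obscured frame
#' @export
applyGPP <- function(frame, persons, params) {
  fs <- frameSizeOf(frame)
  sigma <- params$blurSigmaFrame
  if (is.na(sigma)) sigma <- max(sqrt(fs[1]^2 + fs[2]^2) / 100, 1)
  out <- blurFrame(frame, sigma)
  if (!length(persons)) return(out)
  mask <- overlayMask(persons, params, fs)
  color <- params$overlay$color
  if (length(dim(frame)) == 2) {
    out[mask] <- color[1]
  } else {
    if (length(color) == 1) color <- rep(color, 3)
    for (ch in 1:3) {
      plane <- out[, , ch]
      plane[mask] <- color[ch]
      out[, , ch] <- plane
    }
  }
  out
}

#' Run the full video de-identification stage
#'
#' Pipeline order: track association, gap interpolation (over the full clip
#' frame range, so a person detected late is conservatively covered from the
#' first frame), constant-velocity Kalman smoothing, then per-frame face
#' boxes and PPP or GPP obscuration. Frames where a tracked person yields no
#' face box, or where a gap exceeded `maxGapFrames`, are flagged for QC.
#'
#' @param frames list of frames (matrices or RGB arrays), frame i holding
#'   0-based frame index i - 1
#' @param detections detection list as from [parseDetections()]; frame
#'   indices must fall inside the clip range
#' @param params a [privacyModeParams()]
#' @return list: frames (processed), regions (data.frame log of face boxes),
#'   tracks (smoothed [KeypointTrack-class] list), flags (data.frame of
#'   frames needing QC attention)
#' @export
processVideo <- function(frames, detections, params = privacyModeParams()) {
  nF <- length(frames)
  detFrames <- vapply(detections, `[[`, 0L, "frame")
  if (length(detFrames) && (min(detFrames) < 0 || max(detFrames) >= nF))
    stop(sprintf("detections reference frame %d outside clip range [0, %d]",
                 detFrames[which(detFrames < 0 | detFrames >= nF)[1]],
                 nF - 1L), call. = FALSE)
  tracks <- associateTracks(detections, params$maxMatchDistPx,
                            params$kpConfThreshold)
  tracks <- lapply(tracks, function(tr) {
    tr <- interpolateGaps(tr, params$maxGapFrames,
                          frameRange = c(0L, nF - 1L))
    smoothKalman(tr, params$processNoise, params$measurementNoise)
  })
  regions <- list(); flags <- list(); outFrames <- vector("list", nF)
  for (fi in seq_len(nF)) {
    frame <- frames[[fi]]
    fidx <- fi - 1L
    fs <- frameSizeOf(frame)
    persons <- list(); boxes <- list()
    for (tr in tracks) {
      at <- match(fidx, tr@frameIndex)
      if (is.na(at)) next
      kps <- cbind(tr@coords[at, , 1], tr@coords[at, , 2], tr@conf[at, ])
      if (any(tr@status[at, ] == "missing")) {
        flags[[length(flags) + 1L]] <- data.frame(
          frame = fidx, track = tr@trackId, reason = "gap_exceeded",
          stringsAsFactors = FALSE)
      }
      persons[[length(persons) + 1L]] <- kps
      bbox <- faceBbox(kps, params, fs)
      if (is.null(bbox)) {
        flags[[length(flags) + 1L]] <- data.frame(
          frame = fidx, track = tr@trackId, reason = "no_face_bbox",
          stringsAsFactors = FALSE)
      } else {
        boxes[[length(boxes) + 1L]] <- bbox
        regions[[length(regions) + 1L]] <- data.frame(
          frame = fidx, track = tr@trackId, x0 = bbox["x0"], y0 = bbox["y0"],
          x1 = bbox["x1"], y1 = bbox["y1"], stringsAsFactors = FALSE)
      }
    }
    outFrames[[fi]] <- if (params$mode == "PPP")
      applyPPP(frame, boxes, params)
    else
      applyGPP(frame, persons, params)
  }
  emptyFlags <- data.frame(frame = integer(), track = integer(),
                           reason = character(), stringsAsFactors = FALSE)
  emptyRegions <- data.frame(frame = integer(), track = integer(),
                             x0 = numeric(), y0 = numeric(), x1 = numeric(),
                             y1 = numeric(), stringsAsFactors = FALSE)
  regions <- if (length(regions)) do.call(rbind, regions) else emptyRegions
  flags <- if (length(flags)) do.call(rbind, flags) else emptyFlags
  rownames(regions) <- NULL; rownames(flags) <- NULL
  list(frames = outFrames, regions = regions, tracks = tracks, flags = flags)
}

#' Read/write a PNG frame sequence
#'
#' Frames are numbered `frame_000000.png` from 0; values are 8-bit on disk.
#' @param dir directory of the sequence
#' @export
readFrames <- function(dir) {
  files <- sort(list.files(dir, pattern = "^frame_\\d+\\.png$",
                           full.names = TRUE))
  lapply(files, png::readPNG)
}

#' @rdname readFrames
#' @param frames list of frames
#' @export
writeFrames <- function(frames, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(frames))
    png::writePNG(frames[[i]],
                  file.path(dir, sprintf("frame_%06d.png", i - 1L)))
  invisible(dir)
}
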