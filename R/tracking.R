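#' Parse a pose detections document
#'
#' Schema: `[{"frame": int, "persons": [{"keypoints": [[x, y, conf] x 17]}]}]`
#' with 0-based frame indices and keypoints in COCO order
#' ([cocoKeypointNames()]).
#'
#' @param x path to a JSON file or a JSON string
#' @return list with one element per frame (sorted by frame index):
#'   `list(frame = int, persons = list of 17x3 matrices)`
#' @export
parseDetections <- function(x) {
  txt <- if (length(x) == 1 && !grepl("^\\s*\\[", x) && file.exists(x))
    paste(readLines(x, warn = FALSE), collapse = "\n") else x
  doc <- jsonlite::fromJSON(txt, simplifyVector = FALSE)
  out <- lapply(doc, function(fr) {
    persons <- lapply(fr$persons, function(p) {
      m <- do.call(rbind, lapply(p$keypoints, function(kp)
        as.numeric(unlist(kp))))
      if (!identical(dim(m), c(17L, 3L)) && !(nrow(m) == 17 && ncol(m) == 3))
        stop("each person must have exactly 17 [x, y, conf] keypoints",
             call. = FALSE)
      colnames(m) <- c("x", "y", "conf")
      m
    })
    list(frame = as.integer(fr$frame), persons = persons)
  })
  out[order(vapply(out, `[[`, 0L, "frame"))]
}

#' Serialize detections to JSON
#' @param detections detection list as from [parseDetections()]
#' @param path optional output file
#' @export
writeDetections <- function(detections, path = NULL) {
  doc <- lapply(detections, function(fr) {
    list(frame = fr$frame, persons = lapply(fr$persons, function(m) {
      list(keypoints = lapply(seq_len(nrow(m)), function(i)
        as.numeric(m[i, ])))
    }))
  })
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) { writeLines(json, path); return(invisible(path)) }
  as.character(json)
}

#' Construct a KeypointTrack
#'
#' @param trackId integer id
#' @param frameIndex integer vector of 0-based frame indices
#' @param coords `[n, 17, 2]` array of (x, y)
#' @param conf `[n, 17]` confidence matrix (default 1)
#' @param status `[n, 17]` status matrix (default "observed")
#' @return a [KeypointTrack-class]
#' @export
keypointTrack <- function(trackId, frameIndex, coords, conf = NULL,
                          status = NULL) {
  n <- length(frameIndex)
  if (is.null(conf)) conf <- matrix(1, n, 17L)
  if (is.null(status)) status <- matrix("observed", n, 17L)
  new("KeypointTrack", trackId = as.integer(trackId),
      frameIndex = as.integer(frameIndex), coords = coords, conf = conf,
      status = status)
}

detCentroid <- function(m, confThreshold) {
  keep <- m[, 3] >= confThreshold
  if (!any(keep)) keep <- rep(TRUE, nrow(m))
  c(mean(m[keep, 1]), mean(m[keep, 2]))
}

#' Associate per-frame detections into per-person tracks
#'
#' Greedy nearest-centroid matching with a distance gate: at each frame,
#' detection/track pairs are matched in ascending order of centroid distance
#' (centroids over keypoints at or above `confThreshold`); a detection
#' farther than `maxMatchDistPx` from every live track starts a new track.
#' Deterministic; track ids are assigned in creation order starting at 1.
#'
#' @param detections detection list as from [parseDetections()]
#' @param maxMatchDistPx association distance gate in pixels
#' @param confThreshold keypoint confidence cutoff for the centroid
#' @return list of [KeypointTrack-class], ordered by track id
#' @export
associateTracks <- function(detections, maxMatchDistPx = 50,
                            confThreshold = 0.3) {
  tracks <- list()   # each: list(id, lastCentroid, frames, kps)
  for (fr in detections) {
    persons <- fr$persons
    if (!length(persons)) next
    cents <- lapply(persons, detCentroid, confThreshold = confThreshold)
    nT <- length(tracks)
    assigned <- rep(NA_integer_, length(persons))
    if (nT) {
      d <- matrix(Inf, length(persons), nT)
      for (i in seq_along(persons)) for (j in seq_len(nT))
        d[i, j] <- sqrt(sum((cents[[i]] - tracks[[j]]$lastCentroid)^2))
      repeat {
        if (!any(is.finite(d)) || min(d) > maxMatchDistPx) break
        ij <- arrayInd(which.min(d), dim(d))
        assigned[ij[1]] <- ij[2]
        d[ij[1], ] <- Inf
        d[, ij[2]] <- Inf
      }
    }
    for (i in seq_along(persons)) {
      j <- assigned[i]
      if (is.na(j)) {
        j <- length(tracks) + 1L
        tracks[[j]] <- list(id = j, lastCentroid = cents[[i]],
                            frames = integer(), kps = list())
      }
      tracks[[j]]$lastCentroid <- cents[[i]]
      tracks[[j]]$frames <- c(tracks[[j]]$frames, fr$frame)
      tracks[[j]]$kps <- c(tracks[[j]]$kps, list(persons[[i]]))
    }
  }
  lapply(tracks, function(tr) {
    n <- length(tr$frames)
    coords <- array(NA_real_, c(n, 17L, 2L))
    conf <- matrix(NA_real_, n, 17L)
    for (k in seq_len(n)) {
      coords[k, , 1] <- tr$kps[[k]][, 1]
      coords[k, , 2] <- tr$kps[[k]][, 2]
      conf[k, ] <- tr$kps[[k]][, 3]
    }
    new("KeypointTrack", trackId = tr$id, frameIndex = as.integer(tr$frames),
        coords = coords, conf = conf,
        status = matrix("observed", n, 17L))
  })
}

#' Fill detection gaps in a track by linear interpolation
#'
#' Interior gaps of at most `maxGapFrames` missing frames are filled
#' per-coordinate by linear interpolation between the flanking observations
#' (status "interpolated", confidence the minimum of the flanks). Leading
#' and trailing gaps within `frameRange` are filled by constant extension of
#' the nearest observation. Interior gaps longer than `maxGapFrames` are
#' kept, with status "missing" and confidence 0, for the QC stage to flag.
#'
#' @param track a [KeypointTrack-class] with at least one observed frame
#' @param maxGapFrames longest interior gap that will be interpolated
#' @param frameRange length-2 integer vector of the frame range to cover;
#'   default the track's own observed range
#' @return a [KeypointTrack-class] with contiguous frames over `frameRange`
#' @export
interpolateGaps <- function(track, maxGapFrames = 30, frameRange = NULL) {
  stopifnot(is(track, "KeypointTrack"))
  if (!length(track@frameIndex)) stop("track has no observed frames",
                                      call. = FALSE)
  if (is.null(frameRange)) frameRange <- range(track@frameIndex)
  grid <- frameRange[1]:frameRange[2]
  n <- length(grid)
  pos <- match(grid, track@frameIndex)
  coords <- array(NA_real_, c(n, 17L, 2L))
  conf <- matrix(0, n, 17L)
  status <- matrix("missing", n, 17L)
  obs <- !is.na(pos)
  coords[obs, , ] <- track@coords[pos[obs], , , drop = FALSE]
  conf[obs, ] <- track@conf[pos[obs], ]
  status[obs, ] <- track@status[pos[obs], ]
  if (!all(obs)) {
    obsIdx <- which(obs)
    runs <- rle(!obs)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    for (ri in seq_along(runs$lengths)) {
      if (!runs$values[ri]) next
      a <- starts[ri]; b <- ends[ri]
      before <- obsIdx[obsIdx < a]
      after <- obsIdx[obsIdx > b]
      if (!length(before)) {            # leading gap: constant extension
        src <- min(after)
        for (g in a:b) {
          coords[g, , ] <- coords[src, , ]
          conf[g, ] <- conf[src, ]
          status[g, ] <- "interpolated"
        }
      } else if (!length(after)) {      # trailing gap: constant extension
        src <- max(before)
        for (g in a:b) {
          coords[g, , ] <- coords[src, , ]
          conf[g, ] <- conf[src, ]
          status[g, ] <- "interpolated"
        }
      } else if (b - a + 1L <= maxGapFrames) {
        lo <- max(before); hi <- min(after)
        for (g in a:b) {
          wHi <- (grid[g] - grid[lo]) / (grid[hi] - grid[lo])
          coords[g, , ] <- (1 - wHi) * coords[lo, , ] + wHi * coords[hi, , ]
          conf[g, ] <- pmin(conf[lo, ], conf[hi, ])
          status[g, ] <- "interpolated"
        }
      }                                 # else: left missing, QC flags it
    }
  }
  new("KeypointTrack", trackId = track@trackId, frameIndex = as.integer(grid),
      coords = coords, conf = conf, status = status)
}

# One-dimensional constant-velocity Kalman filter.
#
# State [position, velocity]; transition F = [[1,1],[0,1]]; white-
# acceleration process noise Q = q * [[1/4, 1/2], [1/2, 1]]; observation
# H = [1, 0] with variance R = r. Initialized at the first measurement with
# zero velocity and P = diag(r, 100). Steps without a measurement are
# prediction-only.
kalmanCV1d <- function(z, observed, q, r) {
  n <- length(z)
  Fm <- matrix(c(1, 0, 1, 1), 2, 2)         # column-major: [[1,1],[0,1]]
  Q <- q * matrix(c(0.25, 0.5, 0.5, 1), 2, 2)
  out <- numeric(n)
  i1 <- which(observed)[1]
  if (is.na(i1)) return(rep(NA_real_, n))
  x <- c(z[i1], 0)
  P <- diag(c(r, 100))
  out[seq_len(i1)] <- z[i1]
  if (i1 < n) for (t in (i1 + 1L):n) {
    x <- Fm %*% x
    P <- Fm %*% P %*% t(Fm) + Q
    if (observed[t]) {
      S <- P[1, 1] + r
      K <- P[, 1] / S
      x <- x + K * (z[t] - x[1])
      P <- P - outer(as.numeric(K), P[1, ])
    }
    out[t] <- x[1]
  }
  out
}

#' Kalman-smooth a gap-filled track
#'
#' Filters each of the 34 coordinate series (17 keypoints x {x, y})
#' independently with a constant-velocity Kalman filter (transition
#' `[[1,1],[0,1]]`, white-acceleration process noise
#' `q * [[1/4,1/2],[1/2,1]]`, scalar observation of position with variance
#' `r`, initialized at the first measurement with zero velocity and
#' covariance `diag(r, 100)`). Frames whose status is "missing" carry no
#' measurement: the filter predicts through them and their status becomes
#' "predicted". The frame set is unchanged.
#'
#' @param track a gap-filled [KeypointTrack-class]
#' @param processNoise white-acceleration intensity q (squared pixels)
#' @param measurementNoise observation variance r (squared pixels)
#' @return a [KeypointTrack-class]
#' @export
smoothKalman <- function(track, processNoise = 1, measurementNoise = 4) {
  stopifnot(is(track, "KeypointTrack"))
  if (processNoise <= 0 || measurementNoise <= 0)
    stop("processNoise and measurementNoise must be positive", call. = FALSE)
  n <- length(track@frameIndex)
  coords <- track@coords
  status <- track@status
  for (k in 1:17) {
    observed <- track@status[, k] != "missing"
    for (d in 1:2) {
      z <- track@coords[, k, d]
      z[!observed] <- 0
      coords[, k, d] <- kalmanCV1d(z, observed, processNoise,
                                   measurementNoise)
    }
    status[!observed, k] <- "predicted"
  }
  new("KeypointTrack", trackId = track@trackId,
      frameIndex = track@frameIndex, coords = coords, conf = track@conf,
      status = status)
}
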