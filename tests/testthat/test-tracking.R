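simplePerson <- function(cx, cy, conf = 0.9) {
  m <- cbind(cx + seq(-8, 8, length.out = 17),
             cy + seq(-20, 20, length.out = 17), conf)
  colnames(m) <- c("x", "y", "conf")
  m
}

test_that("one smoothly moving person yields exactly one full-length track", {
  det <- lapply(0:99, function(f)
    list(frame = f, persons = list(simplePerson(10 + f, 50))))
  tracks <- associateTracks(det, maxMatchDistPx = 50)
  expect_length(tracks, 1)
  expect_length(trackFrames(tracks[[1]]), 100)
})

test_that("two well-separated crossing persons keep their identities", {
  spec <- fixtureSpec(seed = 13, durationS = 2, nFrames = 50, nPersons = 2,
                      dropoutRate = 0, jitterSd = 0.3)
  clip <- genPoseClip(spec)
  tracks <- associateTracks(clip$detections, maxMatchDistPx = 20)
  expect_length(tracks, 2)
  # each track's trajectory matches one ground-truth person throughout
  for (p in 1:2) {
    tr <- tracks[[p]]
    err <- vapply(seq_along(trackFrames(tr)), function(i) {
      f <- trackFrames(tr)[i] + 1
      max(abs(tr@coords[i, , 1] - clip$truth[[p]][f, , 1]))
    }, 0)
    expect_lt(max(err), 3)
  }
})

test_that("an empty frame leaves a gap without breaking the track", {
  det <- lapply(0:9, function(f) {
    if (f == 5) list(frame = f, persons = list())
    else list(frame = f, persons = list(simplePerson(20 + f, 40)))
  })
  tracks <- associateTracks(det, 50)
  expect_length(tracks, 1)
  expect_false(5L %in% trackFrames(tracks[[1]]))
  expect_length(associateTracks(list(), 50), 0)
})

test_that("interior gaps are filled on the exact connecting line", {
  coords <- array(NA_real_, c(2, 17, 2))
  coords[1, , 1] <- 0; coords[1, , 2] <- 0
  coords[2, , 1] <- 4; coords[2, , 2] <- 8
  tr <- keypointTrack(1L, c(0L, 4L), coords)
  filled <- interpolateGaps(tr, maxGapFrames = 30)
  expect_identical(trackFrames(filled), 0:4)
  expect_equal(filled@coords[2:4, 1, 1], c(1, 2, 3))
  expect_equal(filled@coords[2:4, 1, 2], c(2, 4, 6))
  expect_true(all(filled@status[2:4, ] == "interpolated"))
  expect_true(all(filled@status[c(1, 5), ] == "observed"))
})

test_that("a gapless track is returned unchanged", {
  coords <- array(runif(3 * 17 * 2), c(3, 17, 2))
  tr <- keypointTrack(1L, 0:2, coords)
  filled <- interpolateGaps(tr, 30)
  expect_equal(filled@coords, tr@coords)
  expect_identical(filled@status, tr@status)
})

test_that("leading gaps are constant-extended from the first observation", {
  coords <- array(5, c(1, 17, 2))
  tr <- keypointTrack(1L, 3L, coords)
  filled <- interpolateGaps(tr, 30, frameRange = c(0L, 3L))
  expect_identical(trackFrames(filled), 0:3)
  expect_true(all(filled@coords[1:3, , ] == 5))
  expect_true(all(filled@status[1:3, ] == "interpolated"))
})

test_that("gaps beyond the limit stay missing for QC", {
  coords <- array(NA_real_, c(2, 17, 2))
  coords[1, , ] <- 0; coords[2, , ] <- 10
  tr <- keypointTrack(1L, c(0L, 10L), coords)
  filled <- interpolateGaps(tr, maxGapFrames = 5)
  expect_true(all(filled@status[2:10, ] == "missing"))
  expect_error(interpolateGaps(keypointTrack(1L, integer(),
                                             array(0, c(0, 17, 2))), 5),
               "no observed")
})

test_that("Kalman filtering matches a hand-computed recursion to 1e-9", {
  z <- c(1.0, 2.2, 2.9, 4.3, 4.9)
  want <- handKalman(z, q = 1, r = 4)
  coords <- array(0, c(5, 17, 2))
  coords[, , 1] <- matrix(z, 5, 17)
  coords[, , 2] <- matrix(z, 5, 17)
  tr <- keypointTrack(1L, 0:4, coords)
  sm <- smoothKalman(tr, processNoise = 1, measurementNoise = 4)
  expect_equal(sm@coords[, 1, 1], want, tolerance = 1e-9)
  expect_equal(sm@coords[, 9, 2], want, tolerance = 1e-9)
  expect_identical(trackFrames(sm), trackFrames(tr))
})

test_that("vanishing measurement noise reproduces the observations", {
  set.seed(3)
  z <- cumsum(rnorm(20))
  coords <- array(0, c(20, 17, 2))
  coords[, , 1] <- matrix(z, 20, 17); coords[, , 2] <- 0
  sm <- smoothKalman(keypointTrack(1L, 0:19, coords),
                     processNoise = 1, measurementNoise = 1e-12)
  expect_lt(max(abs(sm@coords[, 1, 1] - z)), 1e-6)
})

test_that("filtering reduces RMSE on noisy constant-velocity motion", {
  wins <- 0L
  for (s in 1:10) {
    set.seed(s)
    truth <- 5 + 0.7 * (0:299)
    z <- truth + rnorm(300, 0, 2)
    coords <- array(0, c(300, 17, 2))
    coords[, , 1] <- matrix(z, 300, 17)
    sm <- smoothKalman(keypointTrack(1L, 0:299, coords), 1, 4)
    rmseF <- sqrt(mean((sm@coords[, 1, 1] - truth)^2))
    rmseR <- sqrt(mean((z - truth)^2))
    if (rmseF < rmseR) wins <- wins + 1L
  }
  expect_equal(wins, 10L)
})

test_that("non-positive noise parameters are rejected", {
  tr <- keypointTrack(1L, 0:1, array(0, c(2, 17, 2)))
  expect_error(smoothKalman(tr, 0, 1), "positive")
  expect_error(smoothKalman(tr, 1, -1), "positive")
})

test_that("detections JSON round-trips through parseDetections", {
  det <- lapply(0:3, function(f)
    list(frame = f, persons = if (f == 2) list() else
      list(simplePerson(30 + f, 40))))
  back <- parseDetections(writeDetections(det))
  expect_length(back, 4)
  expect_equal(back[[1]]$persons[[1]], det[[1]]$persons[[1]],
               ignore_attr = TRUE)
  expect_length(back[[3]]$persons, 0)
})
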