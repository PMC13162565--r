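faceKps <- function(nose, eyes, ears, conf = 0.9) {
  m <- matrix(0, 17, 3)
  m[1, 1:2] <- nose
  m[2, 1:2] <- eyes[[1]]; m[3, 1:2] <- eyes[[2]]
  m[4, 1:2] <- ears[[1]]; m[5, 1:2] <- ears[[2]]
  m[1:5, 3] <- conf
  m
}

test_that("face bbox is the hull of confident facial points plus margin", {
  kps <- faceKps(c(50, 40), list(c(45, 35), c(55, 35)),
                 list(c(40, 38), c(60, 38)))
  p0 <- privacyModeParams("PPP", bboxMarginFrac = 0)
  bb <- faceBbox(kps, p0, c(200, 200))
  expect_equal(unname(bb), c(40, 35, 60, 40))
  # margin expands every side by marginFrac * diagonal
  pm <- privacyModeParams("PPP", bboxMarginFrac = 0.25)
  d <- sqrt(20^2 + 5^2)
  expect_equal(unname(faceBbox(kps, pm, c(200, 200))),
               c(40, 35, 60, 40) + 0.25 * d * c(-1, -1, 1, 1))
})

test_that("low-confidence faces yield NULL and coincident points a floor box", {
  kps <- faceKps(c(50, 40), list(c(45, 35), c(55, 35)),
                 list(c(40, 38), c(60, 38)), conf = 0.1)
  p <- privacyModeParams("PPP")
  expect_null(faceBbox(kps, p, c(200, 200)))
  co <- faceKps(c(100, 100), list(c(100, 100), c(100, 100)),
                list(c(100, 100), c(100, 100)))
  bb <- faceBbox(co, privacyModeParams("PPP", minBoxPx = 16), c(300, 300))
  expect_equal(unname(bb), c(92, 92, 108, 108))
})

test_that("bboxes are clipped to the frame", {
  kps <- faceKps(c(2, 2), list(c(0, 1), c(4, 1)), list(c(-1, 2), c(5, 2)))
  bb <- faceBbox(kps, privacyModeParams("PPP"), c(50, 60))
  expect_gte(bb[["x0"]], 0); expect_gte(bb[["y0"]], 0)
  expect_lte(bb[["x1"]], 60); expect_lte(bb[["y1"]], 50)
})

test_that("PPP leaves everything outside the regions bit-identical", {
  set.seed(5)
  frame <- matrix(runif(96 * 128), 96, 128)
  p <- privacyModeParams("PPP", blurSigmaFace = 2)
  expect_identical(applyPPP(frame, list(), p), frame)
  bb <- c(x0 = 30, y0 = 20, x1 = 60, y1 = 50)
  out <- applyPPP(frame, list(bb), p)
  inside <- matrix(FALSE, 96, 128)
  inside[21:50, 31:60] <- TRUE
  expect_identical(out[!inside], frame[!inside])
  expect_false(identical(out[inside], frame[inside]))
})

test_that("blurring a constant frame is the identity and matches direct convolution", {
  flat <- matrix(0.4, 40, 40)
  p <- privacyModeParams("PPP", blurSigmaFace = 2)
  bb <- c(x0 = 5, y0 = 5, x1 = 35, y1 = 35)
  expect_equal(applyPPP(flat, list(bb), p), flat, tolerance = 1e-7)
  # checkerboard region: equality with the naive convolution oracle
  cb <- outer(1:40, 1:40, function(r, c) (r + c) %% 2) * 0.6 + 0.2
  out <- applyPPP(cb, list(bb), p)
  want <- naiveGaussBlur(cb, 2)
  expect_equal(out[6:35, 6:35], want[6:35, 6:35], tolerance = 1e-6)
  # and variance strictly drops inside
  expect_lt(var(as.vector(out[6:35, 6:35])), var(as.vector(cb[6:35, 6:35])))
})

test_that("GPP blurs everywhere and renders the overlay at keypoint pixels", {
  cb <- outer(1:60, 1:80, function(r, c) (r + c) %% 2) * 0.6 + 0.2
  p <- privacyModeParams("GPP", blurSigmaFrame = 2,
                         overlay = list(pointRadius = 2, lineWidth = 2,
                                        color = 1))
  out0 <- applyGPP(cb, list(), p)
  expect_equal(out0, naiveGaussBlur(cb, 2), tolerance = 1e-6)
  person <- matrix(c(rep(40, 17), rep(30, 17), rep(0.9, 17)), 17, 3)
  person[1, 1:2] <- c(20, 15)
  out <- applyGPP(cb, list(person), p)
  # disc center at the rounded keypoint coordinate carries the overlay color
  expect_equal(out[16, 21], 1)
  expect_equal(out[31, 41], 1)
  mask <- overlayMask(list(person), p, c(60, 80))
  expect_true(mask[16, 21])
  expect_equal(out[!mask], naiveGaussBlur(cb, 2)[!mask],
               tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("GPP reduces local variance at every non-overlay pixel", {
  spec <- smallClipSpec(nFrames = 12)
  clip <- genPoseClip(spec)
  p <- privacyModeParams("GPP")
  fr <- clip$frames[[6]]
  persons <- list(cbind(clip$truth[[1]][6, , ], 1))
  out <- applyGPP(fr, persons, p)
  guard <- dilate1(overlayMask(persons, p, dim(fr)))
  v0 <- localVariance(fr); v1 <- localVariance(out)
  expect_true(all(v1[!guard] < v0[!guard]))
})

test_that("processVideo covers ground-truth landmarks and is local in PPP", {
  spec <- smallClipSpec()
  clip <- genPoseClip(spec)
  res <- processVideo(clip$frames, clip$detections,
                      privacyModeParams("PPP"))
  expect_length(res$frames, length(clip$frames))
  for (f in seq_along(clip$frames)) {
    r <- res$regions[res$regions$frame == f - 1, ]
    expect_equal(nrow(r), 1)
    gt <- clip$truth[[1]][f, 1:5, ]
    expect_true(all(gt[, 1] >= r$x0 & gt[, 1] <= r$x1 &
                      gt[, 2] >= r$y0 & gt[, 2] <= r$y1),
                label = sprintf("landmarks inside bbox at frame %d", f))
    m <- blurCoverageMetric(clip$frames[[f]], res$frames[[f]], list(
      c(x0 = r$x0, y0 = r$y0, x1 = r$x1, y1 = r$y1)))
    expect_identical(m$outsideChanges, 0L)
  }
})

test_that("a zero-person clip passes through PPP untouched", {
  frames <- replicate(5, matrix(runif(30 * 40), 30, 40), simplify = FALSE)
  det <- lapply(0:4, function(f) list(frame = f, persons = list()))
  res <- processVideo(frames, det, privacyModeParams("PPP"))
  expect_identical(res$frames, frames)
  expect_equal(nrow(res$regions), 0)
})

test_that("detections outside the clip range are rejected", {
  frames <- replicate(3, matrix(0.5, 20, 20), simplify = FALSE)
  det <- list(list(frame = 7L, persons = list()))
  expect_error(processVideo(frames, det, privacyModeParams("PPP")),
               "outside clip range")
})

test_that("frame sequences round-trip through PNG", {
  frames <- list(matrix(round(runif(200), 3) * 0, 10, 20) + 0.5,
                 matrix(1, 10, 20))
  d <- withr::local_tempdir()
  writeFrames(frames, d)
  back <- readFrames(d)
  expect_length(back, 2)
  expect_equal(back[[1]], frames[[1]], tolerance = 1 / 254)
})
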