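# Independent oracles used across the suite. Each deliberately re-derives
# its quantity by the most direct method available (sweeps, closed forms,
# naive convolution, scalar recursions) rather than calling the package's
# own implementation path.

# Sort-and-sweep interval merge: merge half-open [start, end) intervals
# whose gap is strictly below `gap`.
sweepMerge <- function(starts, ends, gap) {
  o <- order(starts, ends)
  starts <- starts[o]; ends <- ends[o]
  outS <- starts[1]; outE <- ends[1]
  if (length(starts) > 1) for (i in 2:length(starts)) {
    last <- length(outE)
    if (starts[i] - outE[last] < gap) {
      outE[last] <- max(outE[last], ends[i])
    } else {
      outS <- c(outS, starts[i]); outE <- c(outE, ends[i])
    }
  }
  data.frame(start_ms = as.integer(outS), end_ms = as.integer(outE))
}

# Direct 2-D Gaussian convolution with replicated edges, kernel size
# matched to the implementation's brush (2 * ceiling(3 sigma) + 1).
naiveGaussBlur <- function(m, sigma) {
  half <- ceiling(3 * sigma)
  g <- exp(-((-half:half)^2) / (2 * sigma^2))
  k <- outer(g, g); k <- k / sum(k)
  h <- nrow(m); w <- ncol(m)
  out <- matrix(0, h, w)
  for (r in 1:h) for (c in 1:w) {
    acc <- 0
    for (dr in -half:half) for (dc in -half:half) {
      rr <- min(max(r + dr, 1), h)
      cc <- min(max(c + dc, 1), w)
      acc <- acc + m[rr, cc] * k[dr + half + 1, dc + half + 1]
    }
    out[r, c] <- acc
  }
  out
}

# Scalar-arithmetic constant-velocity Kalman recursion mirroring the
# documented model (F = [[1,1],[0,1]], Q = q [[1/4,1/2],[1/2,1]], H = [1,0],
# x0 = [z1, 0], P0 = diag(r, 100)), written without matrix products.
handKalman <- function(z, q, r) {
  n <- length(z)
  out <- numeric(n)
  xp <- z[1]; xv <- 0
  p11 <- r; p12 <- 0; p22 <- 100
  out[1] <- xp
  if (n > 1) for (t in 2:n) {
    # predict
    xp <- xp + xv
    n11 <- p11 + 2 * p12 + p22 + q * 0.25
    n12 <- p12 + p22 + q * 0.5
    n22 <- p22 + q
    p11 <- n11; p12 <- n12; p22 <- n22
    # update
    s <- p11 + r
    k1 <- p11 / s; k2 <- p12 / s
    innov <- z[t] - xp
    xp <- xp + k1 * innov
    xv <- xv + k2 * innov
    u11 <- p11 - k1 * p11; u12 <- p12 - k1 * p12
    u22 <- p22 - k2 * p12
    p12 <- u12; p11 <- u11; p22 <- u22
    out[t] <- xp
  }
  out
}

# Vectorized 3x3-window local variance (edge windows truncated).
localVariance <- function(m) {
  h <- nrow(m); w <- ncol(m)
  s <- matrix(0, h, w); s2 <- matrix(0, h, w); cnt <- matrix(0, h, w)
  for (dr in -1:1) for (dc in -1:1) {
    rSrc <- max(1, 1 + dr):min(h, h + dr)
    cSrc <- max(1, 1 + dc):min(w, w + dc)
    rDst <- rSrc - dr; cDst <- cSrc - dc
    s[rDst, cDst] <- s[rDst, cDst] + m[rSrc, cSrc]
    s2[rDst, cDst] <- s2[rDst, cDst] + m[rSrc, cSrc]^2
    cnt[rDst, cDst] <- cnt[rDst, cDst] + 1
  }
  (s2 - s^2 / cnt) / (cnt - 1)
}

# Binary dilation of a logical mask by one pixel in the 8-neighbourhood.
dilate1 <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  out <- mask
  for (dr in -1:1) for (dc in -1:1) {
    rSrc <- max(1, 1 + dr):min(h, h + dr)
    cSrc <- max(1, 1 + dc):min(w, w + dc)
    out[rSrc - dr, cSrc - dc] <- out[rSrc - dr, cSrc - dc] | mask[rSrc, cSrc]
  }
  out
}

# Harmonic "vowel" test signal: 8 harmonics with 1/k roll-off.
makeHarmonic <- function(f0, durS = 2, sr = 16000, amp = 0.4) {
  tt <- (0:(durS * sr - 1)) / sr
  s <- 0
  for (k in 1:8) if (k * f0 < sr / 2) s <- s + sin(2 * pi * k * f0 * tt) / k
  audioBuffer(amp * s / max(abs(s)), sr)
}

# Brute-force PHI scan: tests every word n-gram (n up to maxN) against the
# lexicons and every single token against every pattern, with safe-lexicon
# suppression; returns unresolved candidates.
bruteForceCandidates <- function(rows, rules, maxN = 4) {
  toks <- tolower(gsub("^[[:punct:]]+|[[:punct:]]+$", "", rows$text))
  n <- nrow(rows)
  cand <- list()
  isSafe <- function(ix) any(toks[ix] %in% rules@safeLexicon) ||
    paste(toks[ix], collapse = " ") %in% rules@safeLexicon
  for (pi in seq_len(nrow(rules@patterns)))
    for (i in seq_len(n))
      if (toks[i] != "" &&
          grepl(rules@patterns$regex[pi], toks[i], perl = TRUE,
                ignore.case = TRUE) && !isSafe(i))
        cand[[length(cand) + 1]] <- list(
          s = i, e = i, cat = rules@patterns$category[pi], cls = 1,
          pos = pi)
  lexes <- list(list(set = rules@nameLexicon, cat = "NAME", pos = 1),
                list(set = rules@locationLexicon, cat = "LOCATION",
                     pos = 2))
  for (lx in lexes)
    for (len in 1:maxN)
      for (i in seq_len(max(0, n - len + 1))) {
        ix <- i:(i + len - 1)
        if (any(toks[ix] == "")) next
        if (paste(toks[ix], collapse = " ") %in% lx$set && !isSafe(ix))
          cand[[length(cand) + 1]] <- list(s = i, e = ix[len], cat = lx$cat,
                                           cls = 2, pos = lx$pos)
      }
  cand
}

# Resolve brute-force candidates exactly as the engine specifies: longest
# first, then patterns before lexicons, then rule order, then start.
bruteForcePhi <- function(rows, rules, maxN = 4) {
  cand <- bruteForceCandidates(rows, rules, maxN)
  if (!length(cand))
    return(data.frame(word_start_index = integer(),
                      word_end_index = integer(), category = character()))
  df <- do.call(rbind, lapply(cand, function(x)
    data.frame(s = x$s, e = x$e, cat = x$cat, cls = x$cls, pos = x$pos)))
  df <- df[order(-(df$e - df$s), df$cls, df$pos, df$s), ]
  taken <- rep(FALSE, nrow(rows))
  keep <- logical(nrow(df))
  for (i in seq_len(nrow(df))) {
    ix <- df$s[i]:df$e[i]
    if (!any(taken[ix])) { taken[ix] <- TRUE; keep[i] <- TRUE }
  }
  df <- df[keep, ]
  df <- df[order(df$s), ]
  data.frame(word_start_index = rows$index[df$s],
             word_end_index = rows$index[df$e],
             category = df$cat, stringsAsFactors = FALSE)
}

smallClipSpec <- function(seed = 3, nFrames = 60, ...) {
  fixtureSpec(seed = seed, durationS = 2, nFrames = nFrames, fps = 30,
              dropoutRate = 0.08, dropoutMaxGap = 5, ...)
}
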