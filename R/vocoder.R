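# Phase-vocoder backend for voice transformation.
#
# Pitch is shifted by time-stretching with a phase vocoder (identical pitch,
# duration scaled by the ratio) and then resampling the stretched signal
# back to the original sample count, which scales every frequency by exactly
# the requested ratio while conserving duration. The spectral envelope
# (timbre/formant shape) can additionally be warped along the frequency axis
# by a cepstral-lifter gain correction.

hannWindow <- function(n) 0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / n)

wrapPhase <- function(p) ((p + pi) %% (2 * pi)) - pi

# Time-stretch `x` by `stretch` (output duration ~ stretch * input) with a
# constant synthesis hop and fractional analysis hop; pitch is preserved.
pvTimeStretch <- function(x, stretch, nFft = 1024L, hop = 256L) {
  L <- length(x)
  win <- hannWindow(nFft)
  targetLen <- ceiling(L * stretch) + nFft
  K <- ceiling(targetLen / hop) + 1L
  hopAna <- hop / stretch
  omega <- 2 * pi * (0:(nFft - 1)) / nFft   # bin frequency, rad/sample

  out <- numeric((K - 1L) * hop + nFft)
  wsum <- numeric(length(out))
  phPrev <- NULL; posPrev <- NULL; phAcc <- NULL
  xp <- c(x, numeric(nFft))                 # zero tail for the last frames

  for (k in 0:(K - 1L)) {
    pos <- min(floor(k * hopAna), L - 1L)   # integer analysis offset
    frame <- xp[(pos + 1L):(pos + nFft)] * win
    X <- stats::fft(frame)
    mag <- Mod(X); ph <- Arg(X)
    if (is.null(phPrev)) {
      phAcc <- ph
    } else {
      da <- pos - posPrev
      if (da <= 0) da <- 1
      dev <- wrapPhase(ph - phPrev - omega * da)
      trueFreq <- omega + dev / da
      phAcc <- phAcc + trueFreq * hop
    }
    phPrev <- ph; posPrev <- pos
    y <- Re(stats::fft(mag * exp(1i * phAcc), inverse = TRUE)) / nFft
    idx <- (k * hop + 1L):(k * hop + nFft)
    out[idx] <- out[idx] + y * win
    wsum[idx] <- wsum[idx] + win^2
  }
  out / pmax(wsum, 1e-8)
}

# Linear-interpolation resampling: read `x` at fractional step `step`,
# producing exactly `nOut` samples.
resampleStep <- function(x, step, nOut) {
  pos <- 1 + (0:(nOut - 1)) * step
  i0 <- pmin(floor(pos), length(x) - 1)
  frac <- pos - i0
  x[i0] * (1 - frac) + x[i0 + 1] * frac
}

# Pitch-shift by `ratio` with exact length conservation.
pvPitchShift <- function(x, ratio, nFft = 1024L, hop = 256L) {
  if (abs(ratio - 1) < 1e-12) return(x)
  L <- length(x)
  stretched <- pvTimeStretch(x, ratio, nFft, hop)
  needed <- 1 + (L - 1) * ratio + 1
  if (length(stretched) < needed)
    stretched <- c(stretched, numeric(ceiling(needed) - length(stretched)))
  resampleStep(stretched, ratio, L)
}

# Cepstrally smoothed log-magnitude envelope of one spectrum half.
spectralEnvelope <- function(logMag, lifterBins) {
  n <- length(logMag)
  full <- c(logMag, rev(logMag[2:(n - 1)]))
  ceps <- Re(stats::fft(full, inverse = TRUE)) / length(full)
  keep <- numeric(length(full))
  keep[1:lifterBins] <- 1
  keep[(length(full) - lifterBins + 2):length(full)] <- 1
  Re(stats::fft(ceps * keep))[1:n]
}

# Warp the spectral envelope along the frequency axis by factor `warp`
# (> 1 raises formants), leaving fine harmonic structure in place.
pvEnvelopeWarp <- function(x, warp, nFft = 1024L, hop = 256L,
                           lifterBins = 24L) {
  if (abs(warp - 1) < 1e-12) return(x)
  L <- length(x)
  win <- hannWindow(nFft)
  K <- max(1L, ceiling(L / hop))
  out <- numeric((K - 1L) * hop + nFft)
  wsum <- numeric(length(out))
  xp <- c(x, numeric(nFft))
  half <- nFft %/% 2 + 1L
  bins <- 0:(half - 1)
  for (k in 0:(K - 1L)) {
    frame <- xp[(k * hop + 1L):(k * hop + nFft)] * win
    X <- stats::fft(frame)
    mag <- Mod(X[1:half])
    env <- spectralEnvelope(log(mag + 1e-10), lifterBins)
    # envelope value at f/warp: sampling the source envelope compressed or
    # expanded along the bin axis
    srcPos <- bins / warp
    envW <- stats::approx(bins, env, xout = pmin(srcPos, max(bins)),
                          rule = 2)$y
    gain <- exp(clampNum(envW - env, -4, 4))
    gFull <- c(gain, rev(gain[2:(half - 1L)]))
    y <- Re(stats::fft(X * gFull, inverse = TRUE)) / nFft
    idx <- (k * hop + 1L):(k * hop + nFft)
    out[idx] <- out[idx] + y * win
    wsum[idx] <- wsum[idx] + win^2
  }
  (out / pmax(wsum, 1e-8))[1:L]
}

#' Phase-vocoder voice transformation backend
#'
#' The reference vocoder: shifts the fundamental frequency by `f0Ratio`
#' (phase-vocoder time stretch followed by exact-ratio resampling, so the
#' sample count is conserved) and warps the spectral envelope by
#' `envelopeWarp`. Alternative vocoders (e.g. a WORLD-based analysis/
#' synthesis engine) can be supplied to [transformVoice()] as any function
#' with this signature.
#'
#' @param samples numeric sample vector
#' @param sampleRate sampling rate in Hz
#' @param f0Ratio fundamental-frequency scaling factor (> 0)
#' @param envelopeWarp spectral-envelope frequency-axis scaling (> 0)
#' @return numeric vector of the same length as `samples`
#' @export
phaseVocoderBackend <- function(samples, sampleRate, f0Ratio = 1,
                                envelopeWarp = 1) {
  y <- pvPitchShift(samples, f0Ratio)
  y <- pvEnvelopeWarp(y, envelopeWarp)
  stopifnot(length(y) == length(samples))
  y
}
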