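# Fetal QRS detection on the extracted fECG estimate: continuous wavelet
# transform with a Ricker (Mexican-hat) wavelet over a QRS-band of center
# frequencies, a rolling-MAD adaptive threshold, refractory suppression,
# and refinement of each detection to the local extremum of |signal|.

#' Fetal QRS detector configuration
#'
#' @param bandHz center-frequency band of the Ricker wavelet scales, Hz
#'   (QRS energy band).
#' @param nScales number of log-spaced scales across the band.
#' @param thresholdK threshold factor relative to the rolling median
#'   absolute deviation of the aggregated CWT magnitude.
#' @param refractoryMs minimum distance between detections, ms (caps the
#'   detectable rate at `60000/refractoryMs` bpm).
#' @param rollingS rolling window for the adaptive threshold, seconds.
#' @return a list of class `"DetectorConfig"`.
#' @export
detectorConfig <- function(bandHz = c(10, 30), nScales = 8L,
                           thresholdK = 3.0, refractoryMs = 250,
                           rollingS = 2) {
  stopifnot(length(bandHz) == 2, bandHz[1] > 0, bandHz[2] > bandHz[1],
            refractoryMs > 0, rollingS > 0, nScales >= 1)
  structure(list(bandHz = as.numeric(bandHz), nScales = as.integer(nScales),
                 thresholdK = thresholdK, refractoryMs = refractoryMs,
                 rollingS = rollingS),
            class = "DetectorConfig")
}

# Ricker wavelet with peak response at frequency f (Hz), unit L2 norm.
.ricker <- function(f, fs) {
  sigma <- sqrt(2) / (2 * pi * f)
  half <- ceiling(5 * sigma * fs)
  t <- (-half:half) / fs
  w <- (1 - (t / sigma)^2) * exp(-t^2 / (2 * sigma^2))
  w / sqrt(sum(w^2))
}

# Same-length centered convolution via FFT (padded to a highly composite
# length, which is what keeps the per-cell cost of the grid search low).
.convSame <- function(x, w) {
  n <- length(x); m <- length(w)
  L <- stats::nextn(n + m - 1, c(2, 3, 5))
  full <- Re(stats::fft(stats::fft(c(x, numeric(L - n))) *
                        stats::fft(c(w, numeric(L - m))), inverse = TRUE)) / L
  ofs <- (m - 1) %/% 2
  full[(ofs + 1):(ofs + n)]
}

#' Detect fetal R-peaks in an extracted fECG signal
#'
#' Pipeline: (1) mean |CWT| magnitude over Ricker scales spanning
#' `bandHz`; (2) adaptive threshold `thresholdK` times the rolling median
#' absolute deviation; (3) local maxima above threshold; (4) refractory
#' suppression keeping the larger peak; (5) refinement of each detection
#' to the extremum of `|signal|` within +/- 20 ms.  The threshold is
#' relative, so detections are invariant to positive rescaling and to
#' polarity inversion of the input.
#'
#' @param signal extracted fECG estimate, mV.
#' @param fs sampling rate, Hz (must exceed twice the upper band edge).
#' @param config a [detectorConfig()].
#' @return a [BeatAnnotations-class] with label `"detected"`.
#' @examples
#' g <- generateSingleECG(500, 20, hr = 140)
#' det <- detectFQRS(g$signal, 500)
#' length(det)
#' @export
detectFQRS <- function(signal, fs, config = detectorConfig()) {
  stopifnot(inherits(config, "DetectorConfig"))
  if (fs <= 2 * config$bandHz[2])
    stop("fs must exceed twice the upper detector band edge")
  n <- length(signal)
  win <- round(config$rollingS * fs)
  if (n < 2 * win)
    stop("signal shorter than twice the rolling threshold window")
  signal <- as.numeric(signal)
  freqs <- exp(seq(log(config$bandHz[1]), log(config$bandHz[2]),
                   length.out = config$nScales))
  agg <- rowMeans(vapply(freqs,
                         function(f) abs(.convSame(signal, .ricker(f, fs))),
                         numeric(n)))
  k <- min(2L * (win %/% 2L) + 1L, 2L * ((n - 1L) %/% 2L) + 1L)  # odd
  med <- stats::runmed(agg, k, endrule = "constant")
  mad <- stats::runmed(abs(agg - med), k, endrule = "constant")
  thr <- config$thresholdK * mad
  isMax <- c(FALSE, agg[2:(n - 1)] > agg[1:(n - 2)] &
                    agg[2:(n - 1)] >= agg[3:n], FALSE)
  cand <- which(isMax & agg > thr & agg > 0)
  if (!length(cand))
    return(BeatAnnotations(integer(), fs, "detected"))
  refr <- round(config$refractoryMs / 1000 * fs)
  keep <- logical(length(cand))
  ord <- order(agg[cand], decreasing = TRUE)
  taken <- integer()
  for (i in ord) {
    if (!length(taken) || all(abs(cand[i] - taken) >= refr)) {
      keep[i] <- TRUE
      taken <- c(taken, cand[i])
    }
  }
  det <- sort(cand[keep])
  half <- round(0.020 * fs)
  ref <- vapply(det, function(p) {
    lo <- max(1L, p - half); hi <- min(n, p + half)
    lo + which.max(abs(signal[lo:hi])) - 1L
  }, numeric(1))
  ref <- sort(ref)
  # refinement can pull neighbours together; re-apply the refractory rule
  if (length(ref) > 1L) {
    out <- ref[1]
    for (p in ref[-1]) {
      if (p - out[length(out)] >= refr) out <- c(out, p)
      else if (abs(signal[p]) > abs(signal[out[length(out)]]))
        out[length(out)] <- p
    }
    ref <- out
  }
  BeatAnnotations(unique(ref) - 1L, fs, "detected")   # 0-based
}
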