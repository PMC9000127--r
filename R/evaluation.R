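# Beat matching, the Se/PPV/F1 statistics, windowed aggregation, and
# fetal heart-rate trace derivation and comparison.

#' Match detected beats against reference beats
#'
#' Greedy chronological one-to-one matching: each reference beat (in
#' order) is paired with the nearest unmatched detection within
#' `+/- toleranceMs`; unmatched detections are false positives, unmatched
#' references false negatives.  At physiological beat spacing (intervals
#' wider than twice the tolerance) this equals the optimal bipartite
#' matching.
#'
#' @param detected,reference [BeatAnnotations-class] objects at the same fs.
#' @param toleranceMs matching tolerance, ms (default 50, the convention
#'   of the standard challenge scoring).
#' @return list with integer `tp`, `fp`, `fn`, and data.frame `pairs`
#'   (`ref_idx`, `det_idx`, `offset_ms`).
#' @examples
#' r <- BeatAnnotations(c(1000, 2000), fs = 1000)
#' d <- BeatAnnotations(c(1010, 5000), fs = 1000, label = "detected")
#' matchBeats(d, r)[c("tp", "fp", "fn")]   # 1, 1, 1
#' @export
matchBeats <- function(detected, reference, toleranceMs = 50) {
  stopifnot(is(detected, "BeatAnnotations"), is(reference, "BeatAnnotations"))
  if (detected@fs != reference@fs)
    stop("detected and reference sampling rates differ")
  fs <- reference@fs
  tolSamp <- toleranceMs / 1000 * fs
  det <- detected@peaks
  ref <- reference@peaks
  used <- logical(length(det))
  pairs <- list()
  for (i in seq_along(ref)) {
    if (!length(det)) break
    dist <- abs(det - ref[i])
    dist[used] <- Inf
    j <- which.min(dist)           # ties: earlier detection wins
    if (length(j) && dist[j] <= tolSamp) {
      used[j] <- TRUE
      pairs[[length(pairs) + 1L]] <-
        data.frame(ref_idx = ref[i], det_idx = det[j],
                   offset_ms = (det[j] - ref[i]) / fs * 1000)
    }
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs)
           else data.frame(ref_idx = integer(), det_idx = integer(),
                           offset_ms = numeric())
  list(tp = nrow(pairs), fp = as.integer(sum(!used)),
       fn = as.integer(length(ref) - nrow(pairs)), pairs = pairs)
}

#' Sensitivity, positive predictive value, and F1 (percent)
#'
#' `se = 100 TP/(TP+FN)`, `ppv = 100 TP/(TP+FP)`,
#' `f1 = 100 * 2TP/(2TP+FP+FN)` (the harmonic mean of Se and PPV).
#' Undefined ratios (zero denominator) return `NA`.
#'
#' @param tp,fp,fn non-negative counts.
#' @return percentage in `[0, 100]`, or `NA` when undefined.
#' @examples
#' f1(643, 2, 1)    # 99.767...
#' @export
se <- function(tp, fn) {
  if (tp + fn == 0) return(NA_real_)
  100 * tp / (tp + fn)
}

#' @rdname se
#' @export
ppv <- function(tp, fp) {
  if (tp + fp == 0) return(NA_real_)
  100 * tp / (tp + fp)
}

#' @rdname se
#' @export
f1 <- function(tp, fp, fn) {
  if (2 * tp + fp + fn == 0) return(NA_real_)
  100 * 2 * tp / (2 * tp + fp + fn)
}

#' Windowed beat matching
#'
#' Splits the recording into non-overlapping windows from t = 0, matches
#' beats within each window, and micro-averages: aggregate counts are the
#' sums over windows and the aggregate F1 is computed from the summed
#' counts.
#'
#' @inheritParams matchBeats
#' @param windowS window length in seconds (default 60, the 1-minute
#'   optimization window).
#' @return an [EvaluationReport-class].
#' @export
windowedCounts <- function(detected, reference, windowS = 60,
                           toleranceMs = 50) {
  stopifnot(is(detected, "BeatAnnotations"), is(reference, "BeatAnnotations"))
  if (detected@fs != reference@fs)
    stop("detected and reference sampling rates differ")
  fs <- reference@fs
  w <- windowS * fs
  last <- max(c(detected@peaks, reference@peaks, 0))
  nWin <- max(1L, as.integer(last %/% w) + 1L)
  rows <- vector("list", nWin)
  for (k in seq_len(nWin)) {
    lo <- (k - 1) * w; hi <- k * w
    dWin <- detected@peaks[detected@peaks >= lo & detected@peaks < hi]
    rWin <- reference@peaks[reference@peaks >= lo & reference@peaks < hi]
    m <- matchBeats(BeatAnnotations(dWin, fs, "detected"),
                    BeatAnnotations(rWin, fs, "reference"), toleranceMs)
    rows[[k]] <- data.frame(window = k, tp = m$tp, fp = m$fp, fn = m$fn,
                            se = se(m$tp, m$fn), ppv = ppv(m$tp, m$fp),
                            f1 = f1(m$tp, m$fp, m$fn))
  }
  win <- do.call(rbind, rows)
  evaluationReport(sum(win$tp), sum(win$fp), sum(win$fn), windows = win,
                   params = list(window_s = windowS,
                                 tolerance_ms = toleranceMs))
}

#' Score detections against a reference
#'
#' Convenience wrapper around [windowedCounts()] attaching the record id.
#'
#' @inheritParams windowedCounts
#' @param recordId identifier stored in the report.
#' @return an [EvaluationReport-class].
#' @export
evaluateDetections <- function(detected, reference, windowS = 60,
                               toleranceMs = 50, recordId = "record") {
  rep <- windowedCounts(detected, reference, windowS, toleranceMs)
  rep@recordId <- as.character(recordId)
  rep
}

#' Derive a fetal heart-rate trace from R-peaks
#'
#' Instantaneous rate `60 * fs / RR` is placed at each interval midpoint,
#' median-filtered (5-point), linearly resampled onto a uniform 0.25 s
#' grid, and smoothed with a centered moving average of `averagingS`
#' seconds.  Fewer than 2 peaks give an empty trace.
#'
#' @param annotations a [BeatAnnotations-class].
#' @param averagingS averaging window, seconds.
#' @return an [FHRTrace-class].
#' @examples
#' a <- BeatAnnotations(seq(0, 10000, by = 500), fs = 1000)
#' fhrTrace(a)   # flat 120 bpm
#' @export
fhrTrace <- function(annotations, averagingS = 7.5) {
  stopifnot(is(annotations, "BeatAnnotations"))
  p <- annotations@peaks
  fs <- annotations@fs
  if (length(p) < 2L)
    return(new("FHRTrace", time = numeric(), bpm = numeric(),
               averagingS = averagingS))
  rr <- diff(p)
  bpm <- 60 * fs / rr
  tm <- (p[-length(p)] + p[-1]) / 2 / fs
  if (length(bpm) >= 5L)
    bpm <- stats::runmed(bpm, 5L, endrule = "median")
  grid <- seq(ceiling(min(tm) / 0.25) * 0.25,
              floor(max(tm) / 0.25) * 0.25, by = 0.25)
  if (!length(grid))
    return(new("FHRTrace", time = numeric(), bpm = numeric(),
               averagingS = averagingS))
  g <- stats::approx(tm, bpm, xout = grid, rule = 2)$y
  half <- max(0L, round(averagingS / 0.25 / 2))
  sm <- vapply(seq_along(g), function(i) {
    lo <- max(1L, i - half); hi <- min(length(g), i + half)
    mean(g[lo:hi])
  }, numeric(1))
  new("FHRTrace", time = grid, bpm = sm, averagingS = averagingS)
}

#' Compare a fetal heart-rate trace against a reference (CTG) trace
#'
#' Aligns the traces on their common time range (linear interpolation of
#' the reference onto the trace grid) and reports deviation statistics.
#'
#' @param trace,ctg [FHRTrace-class] objects.
#' @param withinBpm tolerance band for the agreement fraction (default
#'   +/- 10 bpm, the clinically quoted band).
#' @return list with `meanAbsDev`, `maxAbsDev` (bpm) and `fractionWithin`.
#' @export
compareFHR <- function(trace, ctg, withinBpm = 10) {
  stopifnot(is(trace, "FHRTrace"), is(ctg, "FHRTrace"))
  lo <- max(min(trace@time), min(ctg@time))
  hi <- min(max(trace@time), max(ctg@time))
  if (!length(trace@time) || !length(ctg@time) || lo > hi)
    stop("traces have no overlapping time range")
  sel <- trace@time >= lo & trace@time <= hi & is.finite(trace@bpm)
  if (!any(sel)) stop("no finite trace values in the overlap")
  ref <- stats::approx(ctg@time, ctg@bpm, xout = trace@time[sel])$y
  dev <- abs(trace@bpm[sel] - ref)
  list(meanAbsDev = mean(dev), maxAbsDev = max(dev),
       fractionWithin = mean(dev <= withinBpm))
}
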