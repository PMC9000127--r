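test_that("beat matching handles identity, partial, and empty cases", {
  r <- BeatAnnotations(c(1000, 2000, 3000), fs = 1000)
  self <- matchBeats(BeatAnnotations(peaks(r), 1000, "detected"), r)
  expect_equal(self[c("tp", "fp", "fn")], list(tp = 3L, fp = 0L, fn = 0L))
  r2 <- BeatAnnotations(c(1000, 2000), fs = 1000)
  d2 <- BeatAnnotations(c(1010, 5000), fs = 1000, label = "detected")
  m <- matchBeats(d2, r2, toleranceMs = 50)
  expect_equal(m[c("tp", "fp", "fn")], list(tp = 1L, fp = 1L, fn = 1L))
  expect_equal(m$pairs$offset_ms, 10)
  empty <- matchBeats(BeatAnnotations(integer(), 1000, "detected"), r)
  expect_equal(empty[c("tp", "fp", "fn")], list(tp = 0L, fp = 0L, fn = 3L))
  expect_error(matchBeats(BeatAnnotations(1, 500, "detected"), r), "differ")
})

test_that("greedy matching equals the exhaustive optimum at physiological spacing", {
  fs <- 1000; tolMs <- 50; tolSamp <- tolMs / 1000 * fs
  set.seed(123)
  for (rep in 1:60) {
    nr <- sample(0:8, 1)
    ref <- sort(sample.int(50, nr)) * (2.5 * tolSamp)  # spacing > 2 tol
    keep <- runif(nr) > 0.2
    det <- ref[keep] + round(runif(sum(keep), -1.4 * tolSamp, 1.4 * tolSamp))
    extra <- sample(0:2, 1)
    if (extra) det <- c(det, sample.int(140 * tolSamp, extra))
    det <- sort(unique(pmax(det, 0)))
    m <- matchBeats(BeatAnnotations(det, fs, "detected"),
                    BeatAnnotations(ref, fs), tolMs)
    expect_identical(m$tp, bruteForceMatch(ref, det, tolSamp))
  }
})

test_that("the statistics reproduce their defining ratios", {
  expect_equal(se(643, 1), 100 * 643 / 644)
  expect_equal(round(se(643, 1), 2), 99.84)
  expect_equal(round(ppv(643, 2), 2), 99.69)
  expect_equal(round(f1(643, 2, 1), 2), 99.77)
  expect_equal(round(f1(593, 1, 51), 2), 95.80)
  expect_equal(se(0, 5), 0); expect_equal(se(5, 0), 100)
  expect_equal(ppv(0, 3), 0); expect_equal(ppv(7, 0), 100)
  expect_equal(f1(0, 0, 5), 0)
  expect_true(is.na(se(0, 0)))
  expect_true(is.na(ppv(0, 0)))
  expect_true(is.na(f1(0, 0, 0)))
})

test_that("F1 is the harmonic mean of Se and PPV, and lies between them", {
  set.seed(9)
  for (i in 1:200) {
    tp <- sample(0:500, 1); fp <- sample(0:100, 1); fn <- sample(0:100, 1)
    if (tp + fp == 0 || tp + fn == 0 || 2 * tp + fp + fn == 0) next
    s <- se(tp, fn); p <- ppv(tp, fp)
    if (s + p == 0) next
    expect_equal(2 * p * s / (p + s), f1(tp, fp, fn), tolerance = 1e-12)
    expect_lte(f1(tp, fp, fn), max(s, p) + 1e-12)
    expect_gte(f1(tp, fp, fn), min(s, p) - 1e-12)
  }
})

test_that("windowed counts conserve totals and respect clean boundaries", {
  fs <- 500
  ref <- BeatAnnotations(seq(200, 500 * 150, by = 215), fs)
  set.seed(4)
  det <- BeatAnnotations(peaks(ref) + sample(-10:10, length(ref), TRUE),
                         fs, "detected")
  rep <- windowedCounts(det, ref, windowS = 60)
  expect_equal(sum(rep@windows$tp), rep@tp)
  expect_equal(sum(rep@windows$fp), rep@fp)
  expect_equal(sum(rep@windows$fn), rep@fn)
  expect_equal(nrow(rep@windows), 3L)
  # no beat within tolerance of a boundary: windowing changes no count
  glob <- matchBeats(det, ref)
  boundary <- 60 * fs
  expect_true(all(abs(peaks(ref) - round(peaks(ref) / boundary) * boundary)
                  > 0.05 * fs))
  expect_equal(rep@tp, glob$tp)
  expect_equal(rep@fp, glob$fp)
  expect_equal(rep@fn, glob$fn)
  # a record shorter than the window yields a single covering window
  short <- windowedCounts(det, ref, windowS = 1e6)
  expect_equal(nrow(short@windows), 1L)
})

test_that("heart-rate traces reproduce constant and jittered rhythms", {
  flat <- fhrTrace(BeatAnnotations(seq(0, 60000, by = 500), fs = 1000))
  expect_true(all(abs(flat@bpm - 120) < 1e-9))
  g <- generateSingleECG(500, 120, 140, 2, seed = 21)
  tr <- fhrTrace(g$annotations)
  expect_lt(abs(mean(tr@bpm) - 140), 2)
  expect_length(fhrTrace(BeatAnnotations(c(10), 500))@bpm, 0L)
})

test_that("trace comparison reports deviations over the overlap", {
  tr <- fhrTrace(BeatAnnotations(seq(0, 60000, by = 500), fs = 1000))
  same <- compareFHR(tr, tr)
  expect_equal(same$meanAbsDev, 0)
  expect_equal(same$fractionWithin, 1)
  shifted <- new("FHRTrace", time = tr@time, bpm = tr@bpm + 5,
                 averagingS = tr@averagingS)
  off <- compareFHR(shifted, tr)
  expect_equal(off$meanAbsDev, 5)
  expect_equal(off$fractionWithin, 1)
  late <- new("FHRTrace", time = tr@time + 1e5, bpm = tr@bpm,
              averagingS = 7.5)
  expect_error(compareFHR(tr, late), "overlap")
})
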