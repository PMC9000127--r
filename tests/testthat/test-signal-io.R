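test_that("CSV records round-trip losslessly with sidecar sampling rate", {
  m <- matrix(c(0.1, -0.2, 0.33, 1e-4, 0, 2.5, -1.25, 0.7, 0.9, 0.11,
                rnorm(10)), ncol = 2)
  rec <- MultichannelRecord(m, fs = 500, channelNames = c("V1", "V2"),
                            recordId = "toy")
  path <- file.path(tempdir(), "toy.csv")
  writeRecord(rec, path)
  back <- readRecord(path)
  expect_equal(nSamples(back), 10L)
  expect_equal(nChannels(back), 2L)
  expect_equal(samplingRate(back), 500)
  expect_equal(channelNames(back), c("V1", "V2"))
  expect_lt(max(abs(sampleMatrix(back) - sampleMatrix(rec))), 1e-9)
  # explicit fs overrides a missing sidecar
  file.remove(paste0(path, ".json"))
  expect_error(readRecord(path), "sampling rate missing")
  expect_equal(samplingRate(readRecord(path, fs = 250)), 250)
})

test_that("non-finite samples are rejected with the offending channel named", {
  path <- file.path(tempdir(), "bad.csv")
  writeLines(c("a,b", "1,2", "NaN,3"), path)
  expect_error(readRecord(path, fs = 100), "channel.*a")
})

test_that("WFDB records round-trip to quantization accuracy", {
  sim <- simulateRecord(syntheticSpec(durationS = 5, fs = 1000, seed = 11))
  base <- file.path(tempdir(), "synth01")
  gain <- 1000
  writeRecord(sim$record, base, format = "wfdb", gain = gain)
  back <- readRecord(paste0(base, ".hea"))
  expect_equal(samplingRate(back), 1000)
  expect_equal(channelNames(back), channelNames(sim$record))
  expect_lt(max(abs(sampleMatrix(back) - sampleMatrix(sim$record))),
            0.5 / gain + 1e-12)
})

test_that("WFDB annotations round-trip exactly against generator truth", {
  sim <- simulateRecord(syntheticSpec(durationS = 20, fs = 1000, seed = 4))
  ann <- sim$fetalAnnotations
  path <- file.path(tempdir(), "synth01.fqrs")
  writeAnnotations(ann, path, format = "wfdb_ann")
  back <- readAnnotations(path, fs = 1000, format = "wfdb_ann")
  expect_identical(peaks(back), peaks(ann))
  expect_equal(length(back), length(ann))
  # long inter-beat gaps exercise the SKIP escape
  sparse <- BeatAnnotations(c(10, 5000, 200000, 200500), fs = 1000)
  writeAnnotations(sparse, path, format = "wfdb_ann")
  expect_identical(peaks(readAnnotations(path, fs = 1000)), peaks(sparse))
})

test_that("text annotations parse, sort, and de-duplicate", {
  p1 <- file.path(tempdir(), "a1.txt")
  writeLines(c("10", "250", "700"), p1)
  expect_identical(peaks(readAnnotations(p1, fs = 500)),
                   c(10L, 250L, 700L))
  p2 <- file.path(tempdir(), "a2.txt")
  writeLines("700,10,250", p2)
  expect_identical(peaks(readAnnotations(p2, fs = 500)),
                   c(10L, 250L, 700L))
  expect_warning(BeatAnnotations(c(5, 5, 9), fs = 10), "duplicate")
  expect_error(BeatAnnotations(c(-1, 5), fs = 10), "non-negative")
  p3 <- file.path(tempdir(), "a3.txt")
  writeLines("-4 10", p3)
  expect_error(readAnnotations(p3, fs = 500), "non-negative")
})

test_that("evaluation reports serialize losslessly and round the displayed F1", {
  rep <- evaluationReport(643, 2, 1, recordId = "r01")
  path <- file.path(tempdir(), "rep.json")
  writeReport(rep, path)
  txt <- paste(readLines(path), collapse = "")
  expect_match(txt, "99.77", fixed = TRUE)
  back <- readReport(path)
  expect_identical(c(back@tp, back@fp, back@fn), c(643L, 2L, 1L))
  # empty report still carries the schema version
  empty <- evaluationReport(0, 0, 0)
  writeReport(empty, path)
  obj <- jsonlite::fromJSON(path)
  expect_match(obj$schema, "report")
  # CSV report is readable and carries the aggregate row
  pcsv <- file.path(tempdir(), "rep.csv")
  writeReport(rep, pcsv, format = "csv")
  df <- read.csv(pcsv)
  expect_equal(df$tp[nrow(df)], 643)
})

test_that("channel subsetting preserves fs and values bit-for-bit", {
  sim <- simulateRecord(syntheticSpec(durationS = 2))
  sub <- subsetChannels(sim$record, c(3, 1))
  expect_identical(sampleMatrix(sub)[, 1],
                   unname(sampleMatrix(sim$record)[, 3]))
  expect_identical(samplingRate(sub), samplingRate(sim$record))
  expect_error(subsetChannels(sim$record, 9), "invalid channel")
})
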