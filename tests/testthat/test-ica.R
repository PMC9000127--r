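test_that("channel subset enumeration matches the closed-form count", {
  expect_length(selectChannelSubsets(6), 57L)          # 2^6 - 6 - 1
  expect_identical(selectChannelSubsets(2), list(c(1L, 2L)))
  expect_length(selectChannelSubsets(4), 11L)          # 2^4 - 4 - 1
  for (n in 2:7)
    expect_length(selectChannelSubsets(n), 2^n - n - 1)
  subs <- selectChannelSubsets(4)
  sizes <- lengths(subs)
  expect_true(!is.unsorted(sizes))                     # ordered by size
  expect_false(anyDuplicated(vapply(subs, paste, "", collapse = ",")) > 0)
  expect_true(all(vapply(subs, function(s) !is.unsorted(s, strictly = TRUE),
                         logical(1))))
  expect_error(selectChannelSubsets(1), "at least")
})

noiselessMixture <- function(seed = 1) {
  m <- generateSingleECG(500, 30, 75, 2, seed = 1)
  f <- generateSingleECG(500, 30, 140, 2, seed = 2)
  A <- matrix(c(0.8, 0.3, 0.4, 0.9), 2)
  list(rec = MultichannelRecord(cbind(m$signal, 0.25 * f$signal) %*% A, 500),
       m = m, f = f)
}

test_that("ICA recovers noiseless instantaneous sources", {
  mx <- noiselessMixture()
  dec <- separateSources(mx$rec, seed = 1)
  S <- components(dec)
  corM <- max(abs(cor(S, mx$m$signal)))
  corF <- max(abs(cor(S, mx$f$signal)))
  expect_gt(corM, 0.95)
  expect_gt(corF, 0.95)
  expect_equal(unname(apply(S, 2, sd)), rep(1, 2), tolerance = 1e-8)
  # polarity contract: the dominant extremum is positive
  expect_true(all(apply(S, 2, function(s) abs(max(s)) >= abs(min(s)))))
})

test_that("separation is deterministic and permutation-invariant", {
  mx <- noiselessMixture()
  d1 <- separateSources(mx$rec, seed = 42)
  d2 <- separateSources(mx$rec, seed = 42)
  expect_identical(d1@unmixing, d2@unmixing)
  perm <- subsetChannels(mx$rec, c(2, 1))
  d3 <- separateSources(perm, seed = 42)
  # same component set up to matching: every component of one run has a
  # near-perfect counterpart in the other
  cc <- abs(cor(components(d1), components(d3)))
  expect_true(all(apply(cc, 1, max) > 0.999))
})

test_that("rank-deficient inputs are rejected", {
  x <- rnorm(1000)
  rec <- MultichannelRecord(cbind(x, 2 * x), 500)
  expect_error(separateSources(rec), "rank-deficient")
})

test_that("roles map the maternal and fetal rhythms", {
  m <- generateSingleECG(500, 30, 75, 2, seed = 3)
  f <- generateSingleECG(500, 30, 140, 2, seed = 4)
  S <- cbind(m$signal / sd(m$signal), f$signal / sd(f$signal))
  mkDec <- function(S) new("ICADecomposition", components = S,
                           unmixing = diag(ncol(S)),
                           subset = seq_len(ncol(S)),
                           roles = rep("unassigned", ncol(S)),
                           diagnostics = data.frame(
                             rate_bpm = rep(NA_real_, ncol(S)),
                             periodicity = rep(NA_real_, ncol(S))),
                           fs = 500)
  dec <- assignRoles(mkDec(S))
  expect_identical(componentRoles(dec), c("mECG*", "aECG*"))
  expect_equal(dec@diagnostics$rate_bpm, c(75, 140), tolerance = 0.05)
  # invariant to permutation and sign flip
  dec2 <- assignRoles(mkDec(cbind(-S[, 2], S[, 1])))
  expect_identical(componentRoles(dec2), c("aECG*", "mECG*"))
  # pure noise carries no rhythm
  set.seed(8)
  noise <- matrix(rnorm(30000), ncol = 2)
  expect_error(assignRoles(mkDec(noise)), "different channel subset")
})

test_that("the exhaustive subset search beats or ties the plain pair", {
  spec <- syntheticSpec(durationS = 60, nChannels = 2, seed = 6)
  sim <- simulateRecord(spec)
  set.seed(31)
  noiseCh <- rnorm(nSamples(sim$record), 0, 0.3)
  rec3 <- MultichannelRecord(cbind(sampleMatrix(sim$record), noiseCh), 500,
                             c("a", "b", "noise"))
  bs <- bestSubset(rec3, sim$fetalAnnotations)
  res12 <- runExtraction(rec3, subset = c(1, 2),
                         reference = sim$fetalAnnotations)
  f12 <- f1(res12$report@tp, res12$report@fp, res12$report@fn)
  expect_gte(bs$f1, f12)
  # a two-channel record has a single valid subset, returned unconditionally
  bs2 <- bestSubset(sim$record, sim$fetalAnnotations)
  expect_identical(bs2$subset, c(1L, 2L))
})
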