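test_that("frozen or unexcited filters pass the primary through", {
  fx <- arFixture()
  for (run in list(lmsKernel(fx$d, fx$x, 5, 0),
                   selmsKernel(fx$d, fx$x, 5, 0),
                   adalineKernel(fx$d, fx$x, 5, 0))) {
    expect_identical(fecgEst(run), fx$d)
    expect_true(all(run@weights == 0))
  }
  z <- numeric(length(fx$d))
  for (run in list(lmsKernel(fx$d, z, 5, 0.05),
                   rlsKernel(fx$d, z, 5, 0.999))) {
    expect_equal(fecgEst(run), fx$d)
    expect_true(all(run@weights == 0))
  }
})

test_that("compiled kernels reproduce the definitional update recursions", {
  set.seed(11)
  d <- rnorm(60); x <- rnorm(60)
  for (cse in list(list(sign = FALSE, bias = FALSE),
                   list(sign = TRUE, bias = FALSE))) {
    ref <- refLmsFamily(d, x, 4, 0.05, cse$sign)
    run <- if (cse$sign) selmsKernel(d, x, 4, 0.05) else
      lmsKernel(d, x, 4, 0.05)
    expect_equal(fecgEst(run), ref$e, tolerance = 1e-12)
    expect_equal(run@weights, ref$w, tolerance = 1e-12)
  }
  refB <- refLmsFamily(d, x, 4, 0.05, FALSE, bias = TRUE)
  runB <- adalineKernel(d, x, 4, 0.05, bias = TRUE)
  expect_equal(fecgEst(runB), refB$e, tolerance = 1e-12)
  expect_equal(runB@weights, refB$w, tolerance = 1e-12)
})

test_that("scalar LMS cancels a perfectly correlated primary", {
  fx <- arFixture(n = 4000)
  run <- lmsKernel(fx$x, fx$x, 1, 0.05)
  tail <- fecgEst(run)[3001:4000]
  expect_lt(sqrt(mean(tail^2)), 0.01 * sqrt(mean(fx$x^2)))
})

test_that("sign-error LMS differs from LMS but shares its saturation limit", {
  fx <- stdAdaptiveFixture()
  l <- lmsKernel(fx$d, fx$x, 5, 0.01)
  s <- selmsKernel(fx$d, fx$x, 5, 0.01)
  expect_false(identical(fecgEst(l), fecgEst(s)))
  # when every error is positive the update equals LMS with e replaced by 1
  d2 <- cumsum(abs(rnorm(50))) + 50
  x2 <- rep(1e-3, 50)
  sref <- refLmsFamily(d2, x2, 2, 0.01, TRUE)
  expect_equal(selmsKernel(d2, x2, 2, 0.01)@weights, sref$w)
  expect_true(all(sign(sref$e) == 1))
})

test_that("ADALINE without bias is bit-identical to LMS", {
  fx <- stdAdaptiveFixture()
  for (p in c(1, 5, 13)) {
    a <- adalineKernel(fx$d, fx$x, p, 0.02)
    l <- lmsKernel(fx$d, fx$x, p, 0.02)
    expect_identical(fecgEst(a), fecgEst(l))
    expect_identical(a@weights, l@weights)
  }
  withBias <- adalineKernel(fx$d, fx$x, 5, 0.02, bias = TRUE)
  expect_false(identical(withBias@weights[1:5],
                         lmsKernel(fx$d, fx$x, 5, 0.02)@weights))
})

test_that("RLS at lam = 1 matches batch least squares", {
  for (M in c(1, 4, 8, 16)) {
    fx <- arFixture(n = 500, M = M)
    run <- rlsKernel(fx$d, fx$x, M, lam = 1, initDelta = 1e-8)
    X <- lagMatrix(fx$x, M)
    wls <- solve(crossprod(X), crossprod(X, fx$d))
    expect_lt(max(abs(run@weights - wls)), 1e-6)
  }
})

test_that("RLS matches the exponentially weighted batch oracle", {
  fx <- arFixture(n = 300)
  for (lam in c(0.95, 0.99, 0.999)) {
    run <- rlsKernel(fx$d, fx$x, 5, lam = lam, initDelta = 0.01)
    expect_lt(max(abs(run@weights - ewlsOracle(fx$d, fx$x, 5, lam, 0.01))),
              1e-6)
  }
})

test_that("FTF agrees with RLS on the well-conditioned fixture", {
  fx <- arFixture(n = 500)
  r <- rlsKernel(fx$d, fx$x, 5, 0.999)
  f <- ftfKernel(fx$d, fx$x, 5, 0.999)
  expect_lt(max(abs(fecgEst(f) - fecgEst(r))), 1e-3)
  expect_identical(f@rescues, 0L)
  raw <- nifECG:::cpp_ftf(fx$d, fx$x, 5L, 0.999, 0.01, 50L)
  expect_true(all(raw$gamma > 0 & raw$gamma <= 1 + 1e-9))
})

test_that("FTF rescues on near-zero excitation and completes", {
  set.seed(1)
  x <- c(rnorm(1000), numeric(4000), rnorm(1000))
  d <- c(rep(0, 2), x[1:5998]) * 0.5 + 0.01 * rnorm(6000)
  run <- ftfKernel(d, x, 8, lam = 0.98)
  expect_gte(run@rescues, 1L)
  expect_true(all(is.finite(fecgEst(run))))
  expect_error(ftfKernel(d, x, 8, lam = 0.98, rescueBudget = 0),
               "rescue budget")
})

test_that("divergent LMS runs raise an error naming the sample", {
  fx <- arFixture(n = 2000)
  expect_error(lmsKernel(fx$d, fx$x, 10, 50), "sample [0-9]+")
})

test_that("every algorithm suppresses the maternal component by 10 dB", {
  fx <- stdAdaptiveFixture()
  base <- maternalLevel(fx$d, fx$x)
  tuned <- list(
    lms = adaptiveConfig("lms", M = 8, mu = 0.02),
    selms = adaptiveConfig("selms", M = 8, mu = 0.005),
    adaline = adaptiveConfig("adaline", p = 8, eta = 0.02),
    rls = adaptiveConfig("rls", M = 8, lam = 0.999),
    ftf = adaptiveConfig("ftf", M = 8, lam = 0.9995))
  for (nm in names(tuned)) {
    run <- runAdaptive(tuned[[nm]], fx$d, fx$x)
    supp <- 20 * log10(base / maternalLevel(fecgEst(run), fx$x))
    expect_gt(supp, 10)
    again <- runAdaptive(tuned[[nm]], fx$d, fx$x)
    expect_identical(fecgEst(run), fecgEst(again))   # purity
  }
})

test_that("configuration validation catches invalid control parameters", {
  expect_error(adaptiveConfig("lms", mu = -1), "mu")
  expect_error(adaptiveConfig("rls", lam = 1.2), "lam")
  expect_error(adaptiveConfig("adaline", eta = 0), "eta")
  expect_error(adaptiveConfig("lms", M = 0), "at least 1")
  expect_error(runAdaptive(adaptiveConfig("lms"), 1:5, 1:4), "equal length")
})
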