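test_that("grids respect the declared parameter ranges", {
  g <- paramGrid("lms")
  expect_identical(g$axis1Name, "mu")
  expect_true(all(g$axis1 > 0 & g$axis1 <= 0.1))
  expect_true(all(g$axis2 %in% c(1, seq(5, 100, 5))))
  gr <- paramGrid("rls")
  expect_identical(gr$axis1Name, "lam")
  expect_true(all(gr$axis1 >= 0.98 & gr$axis1 <= 1))
  ga <- paramGrid("adaline", fine = TRUE)
  expect_identical(ga$axis2, as.numeric(1:100))
  expect_error(paramGrid("lms", axis1 = c(0.5)), "0.1")
  expect_error(paramGrid("rls", axis1 = c(0.5)), "0.9")
  expect_error(paramGrid("lms", axis2 = 150), "1, 100")
})

test_that("cell evaluation is deterministic and survives failed runs", {
  pp <- plantedProblem()
  c1 <- evaluateCell("lms", 0.02, 10, pp$d, pp$x, pp$ann, pp$fs)
  c2 <- evaluateCell("lms", 0.02, 10, pp$d, pp$x, pp$ann, pp$fs)
  expect_identical(c1, c2)
  expect_false(c1$failed)
  # a wildly unstable step size diverges and is flagged, not raised
  bad <- evaluateCell("lms", 0.1, 100,
                      pp$d * 1e4, pp$x * 1e4, pp$ann, pp$fs)
  expect_true(bad$failed)
  expect_true(is.na(bad$f1))
})

test_that("a 1x1 grid returns its only cell as the optimum", {
  pp <- plantedProblem()
  g <- paramGrid("lms", axis1 = 0.02, axis2 = 10)
  surf <- gridSearch(g, pp$d, pp$x, pp$ann, pp$fs)
  opt <- findOptimum(surf)
  expect_equal(unname(opt$params), c(0.02, 10))
  expect_equal(opt$f1, f1Matrix(surf)[1, 1])
})

test_that("checkpointed searches resume to the identical surface", {
  pp <- plantedProblem()
  g <- paramGrid("lms", axis1 = c(0.01, 0.03, 0.06), axis2 = c(5, 20))
  fresh <- gridSearch(g, pp$d, pp$x, pp$ann, pp$fs)
  ck <- file.path(tempdir(), "surf.ck")
  if (file.exists(ck)) file.remove(ck)
  full <- gridSearch(g, pp$d, pp$x, pp$ann, pp$fs, checkpoint = ck)
  expect_identical(f1Matrix(full), f1Matrix(fresh))
  # craft a partial checkpoint holding only the first row, then resume
  st <- readRDS(ck)
  st$nextRow <- 2L
  st$f1[2:3, ] <- NA_real_
  saveRDS(st, ck)
  resumed <- gridSearch(g, pp$d, pp$x, pp$ann, pp$fs, checkpoint = ck)
  expect_identical(f1Matrix(resumed), f1Matrix(fresh))
  expect_identical(resumed@tp, fresh@tp)
  file.remove(ck)
})

mkSurface <- function(f1m, axis1 = seq_len(nrow(f1m)),
                      axis2 = seq_len(ncol(f1m)),
                      axis1Name = "mu", failed = NULL) {
  zi <- matrix(0L, nrow(f1m), ncol(f1m))
  if (is.null(failed)) failed <- matrix(FALSE, nrow(f1m), ncol(f1m))
  new("OptimizationSurface", algorithm = "lms", axis1Name = axis1Name,
      axis2Name = "M", axis1 = as.numeric(axis1),
      axis2 = as.numeric(axis2), f1 = f1m, tp = zi, fp = zi, fn = zi,
      failed = failed)
}

test_that("optimum selection reports plateaus and honours the tie contract", {
  uni <- mkSurface(matrix(c(10, 20, 90, 40), 2))
  expect_equal(unname(findOptimum(uni)$params), c(1, 2))
  plateau <- mkSurface(matrix(100, 3, 3), axis1 = c(0.01, 0.02, 0.03),
                       axis2 = c(5, 10, 15))
  opt <- findOptimum(plateau)
  expect_equal(nrow(opt$ties), 9L)
  expect_equal(unname(opt$params), c(0.01, 5))   # smallest M, smallest mu
  lamSurf <- mkSurface(matrix(100, 2, 2), axis1 = c(0.98, 0.99),
                       axis1Name = "lam")
  expect_equal(unname(findOptimum(lamSurf)$params)[1], 0.99)  # largest lam
  allFail <- mkSurface(matrix(NA_real_, 2, 2),
                       failed = matrix(TRUE, 2, 2))
  expect_error(findOptimum(allFail), "failed")
  # a strictly worse cell never changes the optimum
  worse <- mkSurface(matrix(c(10, 20, 90, 40), 2))
  worse@f1[1, 1] <- 1
  expect_identical(findOptimum(worse)$params, findOptimum(uni)$params)
  # failed cells are excluded even when their stored F1 is maximal
  tricked <- mkSurface(matrix(c(100, 20, 90, 40), 2),
                       failed = matrix(c(TRUE, FALSE, FALSE, FALSE), 2))
  expect_equal(findOptimum(tricked)$f1, 90)
})

test_that("surfaces export and re-import identically in both formats", {
  pp <- plantedProblem()
  g <- paramGrid("lms", axis1 = c(0.01, 0.05), axis2 = c(5, 15))
  surf <- gridSearch(g, pp$d, pp$x, pp$ann, pp$fs)
  for (ext in c("json", "csv")) {
    path <- file.path(tempdir(), paste0("surf.", ext))
    exportSurface(surf, path)
    back <- readSurface(path)
    expect_equal(f1Matrix(back), f1Matrix(surf))
    expect_identical(back@tp, surf@tp)
    expect_identical(back@failed, surf@failed)
    expect_identical(findOptimum(back)$params, findOptimum(surf)$params)
  }
})

test_that("the color scale is monotone in F1", {
  v <- c(0, 12.5, 50, 99.99, 100, NA)
  idx <- f1ColorIndex(v)
  expect_true(all(diff(idx[1:5]) >= 0))
  expect_true(is.na(idx[6]))
  set.seed(2)
  a <- runif(100, 0, 100); b <- runif(100, 0, 100)
  hi <- pmax(a, b); lo <- pmin(a, b)
  expect_true(all(f1ColorIndex(hi) >= f1ColorIndex(lo)))
})
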