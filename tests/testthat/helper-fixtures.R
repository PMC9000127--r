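# Shared fixtures (built once per test run) and small reference
# implementations used as independent oracles.

.fx <- new.env()

# Default synthetic abdominal recording (the study-condition fixture).
defaultSim <- function() {
  if (is.null(.fx$sim)) .fx$sim <- simulateRecord(syntheticSpec())
  .fx$sim
}

# Standard adaptive-block fixture: d = maternal * h + 0.25 * fetal,
# x = clean maternal source, h the record's known 5-tap channel-1 FIR.
stdAdaptiveFixture <- function() {
  if (is.null(.fx$std)) {
    sim <- defaultSim()
    h <- sim$firs$maternal[, 1]
    d <- as.numeric(stats::filter(sim$maternalSource, h, sides = 1))
    d[is.na(d)] <- 0
    .fx$std <- list(d = d + 0.25 * sim$fetalSource, x = sim$maternalSource,
                    h = h, fs = 500, ann = sim$fetalAnnotations)
  }
  .fx$std
}

# Well-conditioned stationary fixture: AR(1) reference through a known FIR
# plus observation noise.
arFixture <- function(n = 500, M = 5, seed = 7) {
  key <- paste0("ar", n, "_", M, "_", seed)
  if (is.null(.fx[[key]])) {
    set.seed(seed)
    x <- as.numeric(stats::arima.sim(list(ar = 0.6), n))
    h <- c(0.5, -0.3, 0.2, 0.1, -0.05)[seq_len(min(M, 5))]
    if (M > 5) h <- c(h, rep(0, M - 5))
    d <- as.numeric(stats::filter(x, h, sides = 1))
    d[is.na(d)] <- 0
    .fx[[key]] <- list(d = d + 0.05 * rnorm(n), x = x, h = h)
  }
  .fx[[key]]
}

# Planted-optimum problem: noise-free primary built from the maternal
# source through a spread 5-tap FIR plus the scaled fetal train, so full
# cancellation (and F1 = 100) requires M >= 5.
plantedProblem <- function() {
  if (is.null(.fx$planted)) {
    sim <- simulateRecord(syntheticSpec(durationS = 60))
    h <- c(0.3, -0.45, 0.55, -0.35, 0.4)
    h <- h / sqrt(sum(h^2))
    d <- as.numeric(stats::filter(sim$maternalSource, h, sides = 1))
    d[is.na(d)] <- 0
    .fx$planted <- list(d = d + 0.25 * sim$fetalSource,
                        x = sim$maternalSource, h = h,
                        ann = sim$fetalAnnotations, fs = 500)
  }
  .fx$planted
}

# Delayed-regressor design matrix [x(n), x(n-1), ..., x(n-M+1)].
lagMatrix <- function(x, M) {
  n <- length(x)
  sapply(seq_len(M), function(j) c(rep(0, j - 1), x[seq_len(n - j + 1)]))
}

# Batch oracle for exponentially weighted regularized least squares: the
# normal equations the RLS recursion solves, accumulated directly.
ewlsOracle <- function(d, x, M, lam, delta) {
  X <- lagMatrix(x, M)
  n <- length(d)
  wts <- lam^((n:1) - 1)
  A <- crossprod(X * sqrt(wts)) +
    lam^n * delta * diag(lam^(0:(M - 1)), M)
  solve(A, crossprod(X, wts * d))
}

# Plain R transcription of the LMS-family update equations (the
# definitional recursion, used to check the compiled kernels).
refLmsFamily <- function(d, x, M, mu, sign_error = FALSE, bias = FALSE) {
  L <- if (bias) M + 1 else M
  w <- numeric(L)
  xb <- numeric(L)
  if (bias) xb[L] <- 1
  e <- numeric(length(d))
  for (i in seq_along(d)) {
    if (M > 1) xb[M:2] <- xb[(M - 1):1]
    xb[1] <- x[i]
    e[i] <- d[i] - sum(w * xb)
    g <- if (sign_error) sign(e[i]) else e[i]
    w <- w + mu * g * xb
  }
  list(e = e, w = w)
}

# Exhaustive maximum-cardinality beat matching (oracle for matchBeats):
# recursion over references, each either unmatched or paired with any
# unused detection within tolerance.
bruteForceMatch <- function(ref, det, tolSamp) {
  best <- function(i, used) {
    if (i > length(ref)) return(0L)
    top <- best(i + 1L, used)                  # leave ref i unmatched
    for (j in seq_along(det)) {
      if (!used[j] && abs(det[j] - ref[i]) <= tolSamp) {
        used[j] <- TRUE
        top <- max(top, 1L + best(i + 1L, used))
        used[j] <- FALSE
      }
    }
    top
  }
  best(1L, logical(length(det)))
}

# Residual maternal level in a signal: RMS of its projection onto the
# delayed maternal source subspace over the final half of the record.
maternalLevel <- function(sig, m, M = 8) {
  X <- lagMatrix(m, M)
  half <- (length(sig) %/% 2):length(sig)
  fit <- stats::lm.fit(X[half, , drop = FALSE], sig[half])
  sqrt(mean(fit$fitted.values^2))
}
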