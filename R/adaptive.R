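# Adaptive cancellation block: primary input d = aECG*, reference input
# x = mECG*, output fECG_est = a priori error e(n) = d(n) - w(n-1)' x_vec(n).
# Five interchangeable kernels (compiled): LMS, Sign-Error LMS, ADALINE,
# exponentially weighted RLS, and the fast transversal filter (FTF).

#' Adaptive filter configuration
#'
#' @param algorithm one of `"lms"`, `"selms"`, `"adaline"`, `"rls"`, `"ftf"`.
#' @param M filter length in taps (the filter order is `N = M - 1`); for
#'   ADALINE the equivalent parameter is the input space `p`.
#' @param mu step size (LMS / Sign-Error LMS), > 0.
#' @param lam forgetting factor (RLS / FTF), in (0, 1].
#' @param eta ADALINE learning rate, > 0.
#' @param p ADALINE input space (tap count); defaults to `M`.
#' @param initDelta RLS/FTF inverse-correlation seed: `P(0)` is
#'   `(1/initDelta)` times a lambda-tapered diagonal (the identity at
#'   `lam = 1`).
#' @param bias include a trainable ADALINE bias weight (default off; with
#'   bias off ADALINE is numerically identical to LMS with `M = p`,
#'   `mu = eta`).
#' @param rescueBudget maximum FTF rescue re-initializations before an
#'   instability error is raised.
#' @return a list of class `"AdaptiveConfig"`.
#' @export
adaptiveConfig <- function(algorithm = c("lms", "selms", "adaline", "rls",
                                         "ftf"),
                           M = 10L, mu = 0.01, lam = 0.999, eta = 0.01,
                           p = NULL, initDelta = 0.01, bias = FALSE,
                           rescueBudget = 50L) {
  algorithm <- match.arg(algorithm)
  if (is.null(p)) p <- M
  M <- as.integer(M); p <- as.integer(p)
  if (algorithm %in% c("lms", "selms") && !(mu > 0))
    stop("mu must be positive for ", algorithm)
  if (algorithm %in% c("rls", "ftf") && !(lam > 0 && lam <= 1))
    stop("lam must be in (0, 1]")
  if (algorithm == "adaline" && !(eta > 0))
    stop("eta must be positive for adaline")
  if ((if (algorithm == "adaline") p else M) < 1L)
    stop("filter length must be at least 1")
  structure(list(algorithm = algorithm, M = M, mu = mu, lam = lam,
                 eta = eta, p = p, initDelta = initDelta, bias = bias,
                 rescueBudget = as.integer(rescueBudget)),
            class = "AdaptiveConfig")
}

.filterRun <- function(res, algorithm, config) {
  new("FilterRun", fecgEst = as.numeric(res$e),
      prediction = as.numeric(res$y), weights = as.numeric(res$w),
      algorithm = algorithm, config = config,
      rescues = if (is.null(res$rescues)) 0L else as.integer(res$rescues),
      rescueAt = if (is.null(res$rescue_at)) integer()
                 else as.integer(res$rescue_at))
}

#' Least mean squares cancellation
#'
#' `w(n+1) = w(n) + mu * e(n) * x_vec(n)` from zero initial weights; the
#' emitted fECG estimate is the a priori error.  A step size of zero
#' freezes the weights, so `e == d`.
#'
#' @param d primary signal (aECG*), mV.
#' @param x reference signal (mECG*), mV.
#' @param M filter length in taps.
#' @param mu step size.
#' @return a [FilterRun-class].
#' @export
lmsKernel <- function(d, x, M, mu) {
  stopifnot(length(d) == length(x), M >= 1)
  if (mu < 0) stop("mu must be non-negative")
  .filterRun(cpp_lms(as.numeric(d), as.numeric(x), as.integer(M), mu, FALSE),
             "lms", list(M = as.integer(M), mu = mu))
}

#' Sign-error LMS cancellation
#'
#' As [lmsKernel()] but the update is degraded to the sign of the error:
#' `w(n+1) = w(n) + mu * sign(e(n)) * x_vec(n)` with `sign(0) = 0`.
#'
#' @inheritParams lmsKernel
#' @return a [FilterRun-class].
#' @export
selmsKernel <- function(d, x, M, mu) {
  stopifnot(length(d) == length(x), M >= 1)
  if (mu < 0) stop("mu must be non-negative")
  .filterRun(cpp_lms(as.numeric(d), as.numeric(x), as.integer(M), mu, TRUE),
             "selms", list(M = as.integer(M), mu = mu))
}

#' ADALINE cancellation
#'
#' A single linear neuron with `p` delayed inputs (plus an optional bias
#' weight) trained by the delta rule `w <- w + eta * e(n) * x_vec(n)`.
#' With the bias off it is numerically identical to
#' `lmsKernel(M = p, mu = eta)`.
#'
#' @inheritParams lmsKernel
#' @param p input space (number of delayed inputs).
#' @param eta learning rate.
#' @param bias include a trainable bias weight.
#' @return a [FilterRun-class].
#' @export
adalineKernel <- function(d, x, p, eta, bias = FALSE) {
  stopifnot(length(d) == length(x), p >= 1)
  if (eta < 0) stop("eta must be non-negative")
  .filterRun(cpp_adaline(as.numeric(d), as.numeric(x), as.integer(p), eta,
                         isTRUE(bias)),
             "adaline",
             list(p = as.integer(p), eta = eta, bias = isTRUE(bias)))
}

#' Recursive least squares cancellation
#'
#' Standard exponentially weighted RLS with a priori error:
#' `k(n) = P(n-1) x_vec / (lam + x_vec' P(n-1) x_vec)`,
#' `w(n) = w(n-1) + k(n) e(n)`,
#' `P(n) = (P(n-1) - k(n) x_vec' P(n-1)) / lam`, starting from
#' `P(0) = (1/initDelta) diag(1, lam, ..., lam^(M-1))` (the identity
#' scaled by `1/initDelta` when `lam = 1`).  At `lam = 1` the terminal
#' weights coincide with the batch least-squares solution as
#' `initDelta -> 0`.
#'
#' @inheritParams lmsKernel
#' @param lam forgetting factor in (0, 1].
#' @param initDelta inverse-correlation seed.
#' @return a [FilterRun-class].
#' @export
rlsKernel <- function(d, x, M, lam = 0.999, initDelta = 0.01) {
  stopifnot(length(d) == length(x), M >= 1, lam > 0, lam <= 1,
            initDelta > 0)
  .filterRun(cpp_rls(as.numeric(d), as.numeric(x), as.integer(M), lam,
                     initDelta),
             "rls", list(M = as.integer(M), lam = lam,
                         initDelta = initDelta))
}

#' Fast transversal filter cancellation
#'
#' O(M)-per-sample exact RLS via forward/backward prediction recursions
#' maintaining the conversion factor `gamma(n)`.  Whenever `gamma` leaves
#' `(0, 1]` or any state variable goes non-finite, the prediction state is
#' re-initialized while the joint-process weights are kept (a "rescue");
#' exceeding `rescueBudget` rescues raises an instability error.
#'
#' @inheritParams rlsKernel
#' @param rescueBudget maximum number of rescues.
#' @return a [FilterRun-class]; slot `rescues` counts re-initializations.
#' @export
ftfKernel <- function(d, x, M, lam = 0.999, initDelta = 0.01,
                      rescueBudget = 50L) {
  stopifnot(length(d) == length(x), M >= 1, lam > 0, lam <= 1,
            initDelta > 0)
  .filterRun(cpp_ftf(as.numeric(d), as.numeric(x), as.integer(M), lam,
                     initDelta, as.integer(rescueBudget)),
             "ftf", list(M = as.integer(M), lam = lam,
                         initDelta = initDelta,
                         rescueBudget = as.integer(rescueBudget)))
}

#' Run the configured adaptive cancellation
#'
#' Dispatches to the kernel named in `config`.  In every case
#' `y(n) = w' x_vec(n)` with `x_vec(n) = [x(n), ..., x(n-M+1)]`
#' (zero-padded history), `e(n) = d(n) - y(n)`, and the returned fECG
#' estimate is `e`.
#'
#' @param config an [adaptiveConfig()].
#' @param d primary signal (aECG*).
#' @param x reference signal (mECG*).
#' @return a [FilterRun-class].
#' @examples
#' sim <- simulateRecord(syntheticSpec(durationS = 10))
#' run <- runAdaptive(adaptiveConfig("rls", M = 5, lam = 0.999),
#'                    d = sim$record@samples[, 1], x = sim$maternalSource)
#' @export
runAdaptive <- function(config, d, x) {
  stopifnot(inherits(config, "AdaptiveConfig"))
  if (length(d) != length(x))
    stop("primary and reference signals must have equal length")
  switch(config$algorithm,
    lms = lmsKernel(d, x, config$M, config$mu),
    selms = selmsKernel(d, x, config$M, config$mu),
    adaline = adalineKernel(d, x, config$p, config$eta, config$bias),
    rls = rlsKernel(d, x, config$M, config$lam, config$initDelta),
    ftf = ftfKernel(d, x, config$M, config$lam, config$initDelta,
                    config$rescueBudget))
}
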