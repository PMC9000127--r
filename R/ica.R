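# Non-adaptive block: FastICA separation of the preprocessed abdominal
# channels into noise / mECG* / aECG* components, the channel-subset
# enumeration, and the exhaustive best-subset search.

#' Enumerate channel subsets entering ICA
#'
#' All subsets of at least `minSize` channels, ordered by size and then
#' lexicographically.  For `minSize = 2` the count is `2^n - n - 1`
#' (six electrodes give 57 combinations).
#'
#' @param nChannels number of channels available.
#' @param minSize smallest subset size (default 2).
#' @return list of sorted integer vectors (1-based channel indices).
#' @examples
#' length(selectChannelSubsets(6))   # 57
#' @export
selectChannelSubsets <- function(nChannels, minSize = 2) {
  nChannels <- as.integer(nChannels)
  minSize <- as.integer(minSize)
  if (nChannels < minSize)
    stop("nChannels (", nChannels, ") must be at least minSize (",
         minSize, ")")
  out <- list()
  for (k in minSize:nChannels) {
    cmb <- utils::combn(nChannels, k, simplify = FALSE)
    out <- c(out, cmb)  # combn is already lexicographic
  }
  lapply(out, as.integer)
}

#' Separate abdominal channels into independent components
#'
#' FastICA (symmetric orthogonalization, tanh contrast) on a channel
#' subset of a preprocessed record, with PCA whitening and a seeded
#' deterministic initialization.  Components are normalized to unit
#' variance with polarity flipped so the largest-magnitude extremum is
#' positive; the number of components equals the subset size.
#'
#' @param record a (preprocessed) [MultichannelRecord-class].
#' @param subset integer vector of 1-based channel indices (length >= 2).
#' @param seed RNG seed for the initial unmixing matrix.
#' @param maxIter maximum FastICA iterations.
#' @param tol convergence tolerance on the unmixing rotation.
#' @return an [ICADecomposition-class] with roles `"unassigned"`.
#' @seealso [assignRoles()]
#' @export
separateSources <- function(record, subset = seq_len(nChannels(record)),
                            seed = 1L, maxIter = 200L, tol = 1e-6) {
  stopifnot(is(record, "MultichannelRecord"))
  subset <- sort(unique(as.integer(subset)))
  if (length(subset) < 2L) stop("subset must contain at least 2 channels")
  if (any(subset < 1L | subset > nChannels(record)))
    stop("subset indices out of range")
  X <- record@samples[, subset, drop = FALSE]
  n <- nrow(X); k <- ncol(X)
  Xc <- scale(X, center = TRUE, scale = FALSE)
  C <- crossprod(Xc) / n
  eg <- eigen(C, symmetric = TRUE)
  if (min(eg$values) < 1e-12 * max(eg$values))
    stop("rank-deficient input: channel subset {",
         paste(subset, collapse = ","), "} carries collinear signals")
  K <- diag(1 / sqrt(eg$values), k) %*% t(eg$vectors)   # whitening, k x k
  Z <- Xc %*% t(K)
  W <- withSeed(seed, matrix(stats::rnorm(k * k), k, k))
  W <- .symOrth(W)
  it <- 0L
  repeat {
    it <- it + 1L
    U <- Z %*% t(W)               # n x k current components
    G <- tanh(U)
    gPrime <- colMeans(1 - G^2)
    W1 <- crossprod(G, Z) / n - diag(gPrime, k) %*% W
    W1 <- .symOrth(W1)
    delta <- max(abs(abs(diag(W1 %*% t(W))) - 1))
    W <- W1
    if (delta < tol) break
    if (it >= maxIter)
      stop("FastICA did not converge after ", it,
           " iterations (last change ", format(delta), ")")
  }
  S <- Z %*% t(W)
  # unit variance + deterministic polarity (largest extremum positive)
  sds <- apply(S, 2L, stats::sd)
  S <- sweep(S, 2L, sds, "/")
  flip <- apply(S, 2L, function(s) if (abs(min(s)) > abs(max(s))) -1 else 1)
  S <- sweep(S, 2L, flip, "*")
  unmix <- diag(flip / sds, k) %*% W %*% K   # S = Xc %*% t(unmix)
  new("ICADecomposition", components = S, unmixing = unmix,
      subset = subset, roles = rep("unassigned", k),
      diagnostics = data.frame(rate_bpm = rep(NA_real_, k),
                               periodicity = rep(NA_real_, k)),
      fs = record@fs)
}

.symOrth <- function(W) {
  s <- svd(W)
  s$u %*% t(s$v)
}

# Autocorrelation-based rhythm diagnostics for one component: dominant
# beat rate (bpm) over a lag window and the periodicity score (peak
# normalized autocorrelation in that window).
.rhythmScore <- function(x, fs, bpmLo, bpmHi) {
  lagLo <- max(2L, floor(60 * fs / bpmHi))
  lagHi <- ceiling(60 * fs / bpmLo)
  lagHi <- min(lagHi, length(x) - 2L)
  if (lagHi <= lagLo) return(c(rate = NA_real_, score = -Inf))
  ac <- stats::acf(x, lag.max = lagHi, plot = FALSE, demean = TRUE)$acf[, 1, 1]
  win <- ac[(lagLo + 1L):(lagHi + 1L)]   # acf[1] is lag 0
  i <- which.max(win)
  lag <- lagLo + i - 1L
  c(rate = 60 * fs / lag, score = win[i])
}

#' Assign mECG*/aECG*/noise roles to ICA components
#'
#' The maternal estimate `mECG*` is the component with the highest
#' periodicity score (autocorrelation peak) whose dominant beat rate falls
#' in the maternal band; the primary input `aECG*` is the remaining
#' component with the strongest periodicity at fetal-band lags (falling
#' back to the highest residual periodicity); everything else is noise.
#' Ties break toward the lower component index.  The assignment is
#' invariant to component permutation and sign.
#'
#' @param decomposition an [ICADecomposition-class].
#' @param maternalBandBpm,fetalBandBpm plausible beat-rate bands, bpm.
#' @param minPeriodicity smallest autocorrelation peak accepted as rhythmic.
#' @return the decomposition with roles and diagnostics filled in.
#' @export
assignRoles <- function(decomposition, maternalBandBpm = c(40, 120),
                        fetalBandBpm = c(100, 200), minPeriodicity = 0.1) {
  stopifnot(is(decomposition, "ICADecomposition"))
  S <- decomposition@components
  fs <- decomposition@fs
  k <- ncol(S)
  full <- t(vapply(seq_len(k), function(j)
    .rhythmScore(S[, j], fs, min(maternalBandBpm[1], 40),
                 max(fetalBandBpm[2], 200)), numeric(2)))
  fet <- t(vapply(seq_len(k), function(j)
    .rhythmScore(S[, j], fs, fetalBandBpm[1], fetalBandBpm[2]), numeric(2)))
  roles <- rep("noise", k)
  inMat <- is.finite(full[, 1]) &
    full[, 1] >= maternalBandBpm[1] & full[, 1] <= maternalBandBpm[2] &
    full[, 2] >= minPeriodicity
  if (!any(inMat))
    stop("no component qualifies as mECG* (no maternal-band rhythm); ",
         "try a different channel subset")
  mIdx <- which(inMat)[which.max(full[inMat, 2])]
  roles[mIdx] <- "mECG*"
  rest <- setdiff(seq_len(k), mIdx)
  fetOk <- rest[fet[rest, 2] >= minPeriodicity]
  aIdx <- if (length(fetOk)) {
    fetOk[which.max(fet[fetOk, 2])]
  } else {
    rest[which.max(full[rest, 2])]
  }
  roles[aIdx] <- "aECG*"
  decomposition@roles <- roles
  decomposition@diagnostics <- data.frame(rate_bpm = full[, 1],
                                          periodicity = full[, 2],
                                          fetal_periodicity = fet[, 2])
  validObject(decomposition)
  decomposition
}

#' Exhaustive channel-subset search
#'
#' Runs the full extraction pipeline for every channel subset and returns
#' the subset maximizing the aggregate F1 against the reference
#' annotations.  Subsets that fail (e.g. no maternal component found) are
#' skipped; equal F1 breaks toward the earlier subset in
#' [selectChannelSubsets()] order.
#'
#' @param record raw [MultichannelRecord-class].
#' @param reference reference [BeatAnnotations-class].
#' @param config pipeline configuration, see [pipelineConfig()].
#' @param minSize smallest subset size.
#' @return list with `subset`, `f1`, and `table` (per-subset results).
#' @seealso [runExtraction()]
#' @export
bestSubset <- function(record, reference, config = pipelineConfig(),
                       minSize = 2) {
  stopifnot(is(record, "MultichannelRecord"))
  subsets <- selectChannelSubsets(nChannels(record), minSize)
  f1s <- rep(NA_real_, length(subsets))
  for (i in seq_along(subsets)) {
    res <- tryCatch(
      runExtraction(record, subset = subsets[[i]], config = config,
                    reference = reference),
      error = function(e) NULL)
    if (!is.null(res) && !is.null(res$report))
      f1s[i] <- f1(res$report@tp, res$report@fp, res$report@fn)
  }
  if (all(is.na(f1s))) stop("extraction failed for every channel subset")
  best <- which(f1s == max(f1s, na.rm = TRUE))[1]
  list(subset = subsets[[best]], f1 = f1s[best],
       table = data.frame(
         subset = vapply(subsets, paste, "", collapse = ","),
         f1 = f1s))
}
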