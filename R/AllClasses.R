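#' @useDynLib nifECG, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @import methods
NULL

#' Multichannel abdominal ECG record
#'
#' Container for a sampled multichannel ECG: a numeric matrix of samples in
#' millivolts (rows are time points, columns are channels), the sampling
#' rate in Hz, channel labels, and a record identifier.
#'
#' @slot samples numeric matrix, `n_samples x n_channels`, in mV.
#' @slot fs sampling rate in Hz.
#' @slot channelNames character vector of channel labels.
#' @slot recordId single string identifying the record.
#'
#' @seealso [MultichannelRecord()], [readRecord()], [bandpassRecord()]
#' @export
setClass("MultichannelRecord",
  representation(samples = "matrix", fs = "numeric",
                 channelNames = "character", recordId = "character"),
  validity = function(object) {
    msg <- character()
    if (!is.numeric(object@samples)) msg <- c(msg, "samples must be numeric")
    if (nrow(object@samples) < 1L) msg <- c(msg, "need at least one sample")
    if (ncol(object@samples) < 1L) msg <- c(msg, "need at least one channel")
    if (length(object@fs) != 1L || !is.finite(object@fs) || object@fs <= 0)
      msg <- c(msg, "fs must be a single positive number")
    if (anyNA(object@samples) || any(!is.finite(object@samples))) {
      bad <- which(apply(object@samples, 2L, function(v) any(!is.finite(v))))
      msg <- c(msg, paste0("non-finite samples in channel(s): ",
                           paste(object@channelNames[bad], collapse = ", ")))
    }
    if (length(object@channelNames) != ncol(object@samples))
      msg <- c(msg, "one channel name per column required")
    if (length(object@recordId) != 1L) msg <- c(msg, "recordId must be a single string")
    if (length(msg)) msg else TRUE
  })

#' Ordered beat annotations
#'
#' Strictly increasing R-peak sample positions (0-based) with the sampling
#' rate they refer to and a label distinguishing reference from detected
#' beat sets.
#'
#' @slot peaks integer vector of 0-based sample indices, strictly increasing.
#' @slot fs sampling rate in Hz.
#' @slot label either `"reference"` or `"detected"`.
#'
#' @seealso [BeatAnnotations()], [readAnnotations()], [matchBeats()]
#' @export
setClass("BeatAnnotations",
  representation(peaks = "integer", fs = "numeric", label = "character"),
  validity = function(object) {
    msg <- character()
    if (length(object@peaks) && any(object@peaks < 0L))
      msg <- c(msg, "peak indices must be non-negative")
    if (is.unsorted(object@peaks, strictly = TRUE))
      msg <- c(msg, "peak indices must be strictly increasing")
    if (length(object@fs) != 1L || !is.finite(object@fs) || object@fs <= 0)
      msg <- c(msg, "fs must be a single positive number")
    if (length(object@label) != 1L ||
        !object@label %in% c("reference", "detected"))
      msg <- c(msg, "label must be 'reference' or 'detected'")
    if (length(msg)) msg else TRUE
  })

#' ICA decomposition of an abdominal record
#'
#' Separated components from the non-adaptive block, the unmixing matrix,
#' the channel subset used, per-component diagnostics (dominant beat rate
#' and periodicity score), and -- after role assignment -- the map from
#' components to \{mECG*, aECG*, noise\}.
#'
#' @slot components numeric matrix, `n_samples x k`, unit-variance components.
#' @slot unmixing `k x k` matrix applied to the centered channel subset.
#' @slot subset integer vector of 1-based channel indices entering ICA.
#' @slot roles character vector, one of `"mECG*"`, `"aECG*"`, `"noise"`, or
#'   `"unassigned"` per component.
#' @slot diagnostics data.frame with columns `rate_bpm` and `periodicity`.
#' @slot fs sampling rate in Hz.
#'
#' @seealso [separateSources()], [assignRoles()]
#' @export
setClass("ICADecomposition",
  representation(components = "matrix", unmixing = "matrix",
                 subset = "integer", roles = "character",
                 diagnostics = "data.frame", fs = "numeric"),
  validity = function(object) {
    msg <- character()
    k <- ncol(object@components)
    if (ncol(object@unmixing) != k || nrow(object@unmixing) != k)
      msg <- c(msg, "unmixing must be k x k")
    if (length(object@roles) != k)
      msg <- c(msg, "one role per component required")
    ok <- object@roles %in% c("mECG*", "aECG*", "noise", "unassigned")
    if (!all(ok)) msg <- c(msg, "invalid role label")
    if (any(object@roles != "unassigned")) {
      if (sum(object@roles == "mECG*") != 1L)
        msg <- c(msg, "exactly one mECG* component required")
      if (sum(object@roles == "aECG*") != 1L)
        msg <- c(msg, "exactly one aECG* component required")
    }
    if (length(msg)) msg else TRUE
  })

#' Result of one adaptive-filter run
#'
#' The error signal e(n) (the estimated fetal ECG), the prediction y(n),
#' the final weight vector, the algorithm and control parameters used, and
#' the rescue log for the fast transversal filter.
#'
#' @slot fecgEst numeric, a priori error signal e(n) in mV (the fECG estimate).
#' @slot prediction numeric, filter output y(n).
#' @slot weights numeric, final tap weights.
#' @slot algorithm one of `"lms"`, `"selms"`, `"adaline"`, `"rls"`, `"ftf"`.
#' @slot config list of control parameters used.
#' @slot rescues integer, number of FTF rescue re-initializations (0 otherwise).
#' @slot rescueAt integer vector of 1-based sample indices of rescues.
#'
#' @seealso [runAdaptive()]
#' @export
setClass("FilterRun",
  representation(fecgEst = "numeric", prediction = "numeric",
                 weights = "numeric", algorithm = "character",
                 config = "list", rescues = "integer", rescueAt = "integer"),
  validity = function(object) {
    msg <- character()
    if (length(object@fecgEst) != length(object@prediction))
      msg <- c(msg, "error and prediction lengths differ")
    if (any(!is.finite(object@weights)))
      msg <- c(msg, "non-finite terminal weights")
    if (length(msg)) msg else TRUE
  })

#' Beat-detection evaluation report
#'
#' TP/FP/FN counts with Se, PPV and F1 (percent), overall and per
#' evaluation window, plus the parameters the report was produced with.
#'
#' @slot tp,fp,fn non-negative integer aggregate counts.
#' @slot windows data.frame with per-window `window`, `tp`, `fp`, `fn`,
#'   `se`, `ppv`, `f1`.
#' @slot params list of evaluation parameters (tolerance, window length, ...).
#' @slot recordId record identifier the report refers to.
#'
#' @seealso [evaluateDetections()], [writeReport()]
#' @export
setClass("EvaluationReport",
  representation(tp = "integer", fp = "integer", fn = "integer",
                 windows = "data.frame", params = "list",
                 recordId = "character"),
  validity = function(object) {
    msg <- character()
    if (any(c(object@tp, object@fp, object@fn) < 0L))
      msg <- c(msg, "counts must be non-negative")
    if (length(msg)) msg else TRUE
  })

#' F1 optimization surface
#'
#' Grid of F1 values (percent) over two adaptive-filter control parameters,
#' with per-cell TP/FP/FN counts and a flag for cells whose filter run
#' failed (e.g. FTF instability).  Rows follow `axis1`, columns `axis2`.
#'
#' @slot algorithm adaptive algorithm the surface belongs to.
#' @slot axis1Name,axis2Name parameter names (e.g. `"mu"` and `"M"`).
#' @slot axis1,axis2 numeric axis value vectors.
#' @slot f1 numeric matrix of F1 percentages (NA where failed/undefined).
#' @slot tp,fp,fn integer matrices of per-cell counts.
#' @slot failed logical matrix marking failed cells.
#'
#' @seealso [gridSearch()], [findOptimum()], [exportSurface()]
#' @export
setClass("OptimizationSurface",
  representation(algorithm = "character",
                 axis1Name = "character", axis2Name = "character",
                 axis1 = "numeric", axis2 = "numeric",
                 f1 = "matrix", tp = "matrix", fp = "matrix", fn = "matrix",
                 failed = "matrix"),
  validity = function(object) {
    msg <- character()
    dm <- c(length(object@axis1), length(object@axis2))
    for (s in c("f1", "tp", "fp", "fn", "failed"))
      if (!identical(dim(slot(object, s)), as.integer(dm)))
        msg <- c(msg, paste0(s, " matrix dimensions must match the axes"))
    if (length(msg)) msg else TRUE
  })

#' Fetal heart-rate trace
#'
#' Smoothed beats-per-minute values on a uniform time grid derived from
#' fetal R-R intervals; gaps are NA.
#'
#' @slot time numeric, time grid in seconds (uniform 0.25 s spacing).
#' @slot bpm numeric, heart rate in beats per minute (NA where undefined).
#' @slot averagingS averaging window in seconds.
#'
#' @seealso [fhrTrace()], [compareFHR()]
#' @export
setClass("FHRTrace",
  representation(time = "numeric", bpm = "numeric", averagingS = "numeric"),
  validity = function(object) {
    if (length(object@time) != length(object@bpm))
      "time and bpm lengths differ" else TRUE
  })
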