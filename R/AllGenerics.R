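#' Accessors for nifECG classes
#'
#' Small accessor generics: `samplingRate()` returns the sampling rate in
#' Hz, `nSamples()`/`nChannels()` the record dimensions, `channelNames()`
#' the channel labels, `sampleMatrix()` the raw sample matrix in mV,
#' `peaks()` the 0-based annotation indices, `components()` the separated
#' ICA component matrix, `componentRoles()` the role map, `fecgEst()` the
#' adaptive filter's error signal, and `f1Matrix()` the optimization
#' surface values.
#'
#' @param object an object of the documented classes.
#' @return the accessed slot value.
#' @name accessors
#' @aliases samplingRate nSamples nChannels channelNames sampleMatrix
#'   peaks components componentRoles fecgEst f1Matrix
NULL

#' @rdname accessors
#' @export
setGeneric("samplingRate", function(object) standardGeneric("samplingRate"))
#' @rdname accessors
#' @export
setGeneric("nSamples", function(object) standardGeneric("nSamples"))
#' @rdname accessors
#' @export
setGeneric("nChannels", function(object) standardGeneric("nChannels"))
#' @rdname accessors
#' @export
setGeneric("channelNames", function(object) standardGeneric("channelNames"))
#' @rdname accessors
#' @export
setGeneric("sampleMatrix", function(object) standardGeneric("sampleMatrix"))
#' @rdname accessors
#' @export
setGeneric("peaks", function(object) standardGeneric("peaks"))
#' @rdname accessors
#' @export
setGeneric("components", function(object) standardGeneric("components"))
#' @rdname accessors
#' @export
setGeneric("componentRoles", function(object) standardGeneric("componentRoles"))
#' @rdname accessors
#' @export
setGeneric("fecgEst", function(object) standardGeneric("fecgEst"))
#' @rdname accessors
#' @export
setGeneric("f1Matrix", function(object) standardGeneric("f1Matrix"))

#' @rdname accessors
setMethod("samplingRate", "MultichannelRecord", function(object) object@fs)
#' @rdname accessors
setMethod("samplingRate", "BeatAnnotations", function(object) object@fs)
#' @rdname accessors
setMethod("samplingRate", "ICADecomposition", function(object) object@fs)
#' @rdname accessors
setMethod("nSamples", "MultichannelRecord",
          function(object) nrow(object@samples))
#' @rdname accessors
setMethod("nChannels", "MultichannelRecord",
          function(object) ncol(object@samples))
#' @rdname accessors
setMethod("channelNames", "MultichannelRecord",
          function(object) object@channelNames)
#' @rdname accessors
setMethod("sampleMatrix", "MultichannelRecord",
          function(object) object@samples)
#' @rdname accessors
setMethod("peaks", "BeatAnnotations", function(object) object@peaks)
#' @rdname accessors
setMethod("components", "ICADecomposition",
          function(object) object@components)
#' @rdname accessors
setMethod("componentRoles", "ICADecomposition", function(object) object@roles)
#' @rdname accessors
setMethod("fecgEst", "FilterRun", function(object) object@fecgEst)
#' @rdname accessors
setMethod("f1Matrix", "OptimizationSurface", function(object) object@f1)

#' @describeIn accessors number of annotated beats.
#' @export
setMethod("length", "BeatAnnotations", function(x) length(x@peaks))

setMethod("show", "MultichannelRecord", function(object) {
  cat("MultichannelRecord '", object@recordId, "': ",
      nrow(object@samples), " samples x ", ncol(object@samples),
      " channels @ ", object@fs, " Hz (",
      sprintf("%.1f", nrow(object@samples) / object@fs), " s)\n",
      "channels: ", paste(object@channelNames, collapse = ", "), "\n",
      sep = "")
})

setMethod("show", "BeatAnnotations", function(object) {
  cat("BeatAnnotations (", object@label, "): ", length(object@peaks),
      " beats @ ", object@fs, " Hz\n", sep = "")
})

setMethod("show", "ICADecomposition", function(object) {
  cat("ICADecomposition: ", ncol(object@components),
      " components from channels {",
      paste(object@subset, collapse = ","), "}\n", sep = "")
  if (nrow(object@diagnostics)) {
    df <- cbind(object@diagnostics, role = object@roles)
    print(df, digits = 3)
  }
})

setMethod("show", "FilterRun", function(object) {
  cat("FilterRun [", object@algorithm, "]: ", length(object@fecgEst),
      " samples, ", length(object@weights), " taps",
      if (object@rescues > 0L) paste0(", ", object@rescues, " rescue(s)"),
      "\n", sep = "")
})

setMethod("show", "EvaluationReport", function(object) {
  cat("EvaluationReport '", object@recordId, "': TP=", object@tp,
      " FP=", object@fp, " FN=", object@fn,
      sprintf("  Se=%.2f%% PPV=%.2f%% F1=%.2f%%",
              se(object@tp, object@fn), ppv(object@tp, object@fp),
              f1(object@tp, object@fp, object@fn)),
      " (", nrow(object@windows), " window(s))\n", sep = "")
})

setMethod("show", "OptimizationSurface", function(object) {
  best <- suppressWarnings(max(object@f1, na.rm = TRUE))
  cat("OptimizationSurface [", object@algorithm, "]: ",
      length(object@axis1), " x ", length(object@axis2), " grid (",
      object@axis1Name, " x ", object@axis2Name, "), ",
      sum(object@failed), " failed cell(s), max F1 = ",
      ifelse(is.finite(best), sprintf("%.2f%%", best), "NA"), "\n", sep = "")
})

setMethod("show", "FHRTrace", function(object) {
  ok <- is.finite(object@bpm)
  cat("FHRTrace: ", length(object@time), " points",
      if (any(ok)) sprintf(", %.1f-%.1f s, mean %.1f bpm",
                           min(object@time), max(object@time),
                           mean(object@bpm[ok])),
      "\n", sep = "")
})
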