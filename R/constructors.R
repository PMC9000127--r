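#' Construct a multichannel ECG record
#'
#' @param samples numeric matrix (`n_samples x n_channels`) in millivolts.
#' @param fs sampling rate in Hz.
#' @param channelNames optional channel labels; defaults to `ch1, ch2, ...`.
#' @param recordId record identifier string.
#' @return a [MultichannelRecord-class] object.
#' @examples
#' rec <- MultichannelRecord(cbind(sin(1:100 / 5), cos(1:100 / 5)), fs = 100)
#' nChannels(rec)
#' @export
MultichannelRecord <- function(samples, fs, channelNames = NULL,
                               recordId = "record") {
  samples <- as.matrix(samples)
  storage.mode(samples) <- "double"
  if (is.null(channelNames))
    channelNames <- colnames(samples)
  if (is.null(channelNames))
    channelNames <- paste0("ch", seq_len(ncol(samples)))
  colnames(samples) <- channelNames
  new("MultichannelRecord", samples = samples, fs = as.numeric(fs),
      channelNames = as.character(channelNames),
      recordId = as.character(recordId))
}

#' Construct a beat annotation set
#'
#' Indices are sorted; duplicates are dropped with a warning; negative
#' indices are an error.
#'
#' @param peaks 0-based R-peak sample indices.
#' @param fs sampling rate in Hz.
#' @param label `"reference"` or `"detected"`.
#' @return a [BeatAnnotations-class] object.
#' @examples
#' BeatAnnotations(c(700, 10, 250), fs = 500)
#' @export
BeatAnnotations <- function(peaks, fs, label = "reference") {
  peaks <- as.numeric(peaks)
  if (anyNA(peaks) || any(peaks < 0))
    stop("annotation indices must be non-negative integers")
  peaks <- as.integer(round(peaks))
  if (anyDuplicated(peaks)) {
    warning("duplicate annotation indices removed")
    peaks <- unique(peaks)
  }
  new("BeatAnnotations", peaks = sort(peaks), fs = as.numeric(fs),
      label = match.arg(label, c("reference", "detected")))
}

#' Keep a subset of channels
#'
#' Per-channel values and the sampling rate are preserved bit-for-bit.
#'
#' @param record a [MultichannelRecord-class].
#' @param channels integer vector of 1-based channel indices or channel names.
#' @return a [MultichannelRecord-class] with the selected channels.
#' @export
subsetChannels <- function(record, channels) {
  stopifnot(is(record, "MultichannelRecord"))
  if (is.character(channels))
    channels <- match(channels, record@channelNames)
  channels <- as.integer(channels)
  if (anyNA(channels) || any(channels < 1L | channels > nChannels(record)))
    stop("invalid channel selection")
  MultichannelRecord(record@samples[, channels, drop = FALSE], record@fs,
                     record@channelNames[channels], record@recordId)
}

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG state.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
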