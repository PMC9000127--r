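#' Read a multichannel ECG record
#'
#' Supports WFDB records (`.hea`/`.dat`, signal format 16) and CSV matrices
#' (one column per channel, header row of channel names).  CSV files carry
#' no sampling rate, so `fs` must come either from a sidecar JSON file
#' (`<path>.json`, key `"fs"`) or from the `fs` argument.  Samples are in
#' millivolts; channel order is preserved.
#'
#' @param path path to the `.hea` file (WFDB) or the `.csv` file.
#' @param format `"auto"` (by extension), `"wfdb"`, or `"csv"`.
#' @param fs sampling rate in Hz, required for CSV when no sidecar exists.
#' @return a [MultichannelRecord-class].
#' @seealso [writeRecord()]
#' @export
readRecord <- function(path, format = c("auto", "wfdb", "csv"), fs = NULL) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "wfdb"
  if (format == "wfdb") return(wfdbReadRecord(path))
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE)
  sidecar <- paste0(path, ".json")
  recordId <- sub("\\.csv$", "", basename(path), ignore.case = TRUE)
  if (file.exists(sidecar)) {
    meta <- jsonlite::fromJSON(sidecar)
    if (is.null(fs)) fs <- meta$fs
    if (!is.null(meta$record_id)) recordId <- meta$record_id
  }
  if (is.null(fs))
    stop("sampling rate missing: supply fs= or a '", basename(sidecar),
         "' sidecar with an \"fs\" key")
  m <- as.matrix(df)
  if (anyNA(m)) {
    bad <- colnames(m)[apply(m, 2L, anyNA)]
    stop("NaN/NA samples in channel(s): ", paste(bad, collapse = ", "))
  }
  MultichannelRecord(m, fs, colnames(df), recordId)
}

#' Write a multichannel ECG record
#'
#' CSV output keeps full double precision (round-trips to well below
#' 1e-9 mV) and writes an `"<path>.json"` sidecar with the sampling rate;
#' WFDB output quantizes to the ADC gain (default 1000 ADU/mV, i.e. 1 uV
#' resolution).
#'
#' @param record a [MultichannelRecord-class].
#' @param path output path (`.csv`, or WFDB base/`.hea` path).
#' @param format `"auto"`, `"wfdb"`, or `"csv"`.
#' @param gain WFDB ADC gain in ADU/mV.
#' @return the main file path written, invisibly.
#' @export
writeRecord <- function(record, path, format = c("auto", "wfdb", "csv"),
                        gain = 1000) {
  stopifnot(is(record, "MultichannelRecord"))
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "wfdb"
  if (format == "wfdb") return(invisible(wfdbWriteRecord(record, path, gain)))
  df <- as.data.frame(record@samples)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(record@channelNames, collapse = ","), con)
  body <- apply(record@samples, 1L,
                function(r) paste(sprintf("%.15g", r), collapse = ","))
  writeLines(body, con)
  jsonlite::write_json(
    list(fs = record@fs, record_id = record@recordId, units = "mV"),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read beat annotations
#'
#' Text annotations are whitespace/comma/newline-separated non-negative
#' 0-based sample indices; WFDB annotations are MIT-format beat files.
#' Indices are sorted and de-duplicated (with a warning on duplicates).
#'
#' @param path annotation file path.
#' @param fs sampling rate (Hz) the indices refer to.
#' @param format `"auto"` (text unless the file is binary), `"wfdb_ann"`,
#'   or `"text"`.
#' @param label `"reference"` or `"detected"`.
#' @return a [BeatAnnotations-class].
#' @seealso [writeAnnotations()]
#' @export
readAnnotations <- function(path, fs, format = c("auto", "wfdb_ann", "text"),
                            label = "reference") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    probe <- readBin(path, "raw", n = min(file.size(path), 256L))
    format <- if (any(probe == as.raw(0)) ||
                  grepl("\\.(atr|qrs|fqrs|ann)$", path))
      "wfdb_ann" else "text"
  }
  if (format == "wfdb_ann") return(wfdbReadAnnotations(path, fs, label))
  txt <- paste(readLines(path, warn = FALSE), collapse = " ")
  tok <- strsplit(txt, "[,;[:space:]]+")[[1]]
  tok <- tok[nzchar(tok)]
  idx <- suppressWarnings(as.numeric(tok))
  if (anyNA(idx)) stop("non-numeric annotation entries in ", path)
  if (any(idx < 0)) stop("annotation indices must be non-negative")
  BeatAnnotations(idx, fs, label)
}

#' Write beat annotations
#'
#' @param ann a [BeatAnnotations-class].
#' @param path output path.
#' @param format `"text"` (one 0-based index per line) or `"wfdb_ann"`.
#' @return `path`, invisibly.
#' @export
writeAnnotations <- function(ann, path, format = c("text", "wfdb_ann")) {
  stopifnot(is(ann, "BeatAnnotations"))
  format <- match.arg(format)
  if (format == "wfdb_ann") return(invisible(wfdbWriteAnnotations(ann, path)))
  writeLines(as.character(ann@peaks), path)
  invisible(path)
}

#' Construct an evaluation report
#'
#' @param tp,fp,fn aggregate beat counts.
#' @param windows optional per-window data.frame (columns `window`, `tp`,
#'   `fp`, `fn`, `se`, `ppv`, `f1`).
#' @param params list of evaluation parameters.
#' @param recordId record identifier.
#' @return an [EvaluationReport-class].
#' @export
evaluationReport <- function(tp, fp, fn, windows = NULL, params = list(),
                             recordId = "record") {
  if (is.null(windows))
    windows <- data.frame(window = integer(), tp = integer(), fp = integer(),
                          fn = integer(), se = numeric(), ppv = numeric(),
                          f1 = numeric())
  new("EvaluationReport", tp = as.integer(tp), fp = as.integer(fp),
      fn = as.integer(fn), windows = windows, params = params,
      recordId = as.character(recordId))
}

#' Write an evaluation report
#'
#' JSON output is a lossless serialization of all counts and the derived
#' Se/PPV/F1 percentages (rounded to 2 decimals for display fields, full
#' precision retained in the counts); CSV output writes the per-window
#' table with an aggregate row.
#'
#' @param report an [EvaluationReport-class].
#' @param path output path.
#' @param format `"json"` or `"csv"`.
#' @return `path`, invisibly.
#' @seealso [readReport()]
#' @export
writeReport <- function(report, path, format = c("json", "csv")) {
  stopifnot(is(report, "EvaluationReport"))
  format <- match.arg(format)
  if (format == "json") {
    obj <- list(
      schema = "nifECG-report-1",
      record_id = report@recordId,
      tp = report@tp, fp = report@fp, fn = report@fn,
      se = unname(round(se(report@tp, report@fn), 2)),
      ppv = unname(round(ppv(report@tp, report@fp), 2)),
      f1 = unname(round(f1(report@tp, report@fp, report@fn), 2)),
      params = report@params,
      windows = report@windows)
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         na = "null", dataframe = "rows")
  } else {
    agg <- data.frame(window = NA_integer_, tp = report@tp, fp = report@fp,
                      fn = report@fn, se = se(report@tp, report@fn),
                      ppv = ppv(report@tp, report@fp),
                      f1 = f1(report@tp, report@fp, report@fn))
    utils::write.csv(rbind(report@windows, agg), path, row.names = FALSE)
  }
  invisible(path)
}

#' Read back a JSON evaluation report
#'
#' @param path path written by [writeReport()] with `format = "json"`.
#' @return an [EvaluationReport-class].
#' @export
readReport <- function(path) {
  obj <- jsonlite::fromJSON(path)
  windows <- if (length(obj$windows)) as.data.frame(obj$windows) else NULL
  tp <- if (is.null(obj$tp)) 0L else obj$tp
  fp <- if (is.null(obj$fp)) 0L else obj$fp
  fn <- if (is.null(obj$fn)) 0L else obj$fn
  evaluationReport(tp, fp, fn, windows, as.list(obj$params),
                   if (is.null(obj$record_id)) "record" else obj$record_id)
}

#' Read a CTG fetal heart-rate trace
#'
#' Plain two-column CSV `(time_s, bpm)`, as exported from cardiotocography
#' monitors for comparison against the fECG-derived trace.
#'
#' @param path CSV path with columns `time_s` and `bpm` (or two unnamed
#'   columns in that order).
#' @return an [FHRTrace-class] (averaging window marked NA).
#' @export
readCTG <- function(path) {
  df <- utils::read.csv(path)
  if (all(c("time_s", "bpm") %in% names(df))) {
    t <- df$time_s; b <- df$bpm
  } else {
    t <- df[[1]]; b <- df[[2]]
  }
  new("FHRTrace", time = as.numeric(t), bpm = as.numeric(b),
      averagingS = NA_real_)
}
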