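# Minimal WFDB support: header/.dat signal files in format 16 (16-bit
# little-endian interleaved samples) and MIT-format beat annotation files.
# Covers what this package writes plus plain format-16 records; sample
# times are 0-based throughout, matching WFDB's own convention.

wfdbWriteRecord <- function(record, path, gain = 1000, fmt = 16L) {
  base <- sub("\\.hea$", "", path)
  name <- basename(base)
  n <- nSamples(record); k <- nChannels(record)
  adc <- round(record@samples * gain)
  if (any(abs(adc) > 32767))
    stop("sample out of 16-bit range at gain ", gain, " ADU/mV")
  storage.mode(adc) <- "integer"
  hea <- c(
    sprintf("%s %d %s %d", name, k, format(record@fs), n),
    sprintf("%s.dat %d %d(0)/mV 16 0 %d 0 0 %s",
            name, fmt, gain, adc[1, ], record@channelNames))
  writeLines(hea, paste0(base, ".hea"))
  con <- file(paste0(base, ".dat"), "wb")
  on.exit(close(con))
  writeBin(as.integer(t(adc)), con, size = 2L, endian = "little")
  invisible(paste0(base, ".hea"))
}

wfdbReadRecord <- function(path) {
  base <- sub("\\.hea$", "", path)
  if (!file.exists(paste0(base, ".hea")))
    stop("WFDB header not found: ", paste0(base, ".hea"))
  lines <- readLines(paste0(base, ".hea"), warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  head <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (length(head) < 4) stop("malformed WFDB header record line")
  k <- as.integer(head[2])
  fs <- as.numeric(sub("/.*$", "", head[3]))  # drop counter-frequency suffix
  n <- as.integer(head[4])
  sig <- lines[2:(1 + k)]
  gains <- numeric(k); baselines <- numeric(k); names <- character(k)
  datf <- character(k)
  for (i in seq_len(k)) {
    tok <- strsplit(trimws(sig[i]), "\\s+")[[1]]
    datf[i] <- tok[1]
    if (as.integer(sub("x.*$", "", tok[2])) != 16L)
      stop("only WFDB signal format 16 is supported (got ", tok[2], ")")
    gspec <- tok[3]
    g <- as.numeric(sub("^([-0-9.eE+]+).*$", "\\1", gspec))
    b <- if (grepl("\\(", gspec))
      as.numeric(sub("^.*\\(([-0-9]+)\\).*$", "\\1", gspec)) else 0
    gains[i] <- if (is.na(g) || g == 0) 200 else g  # WFDB default gain
    baselines[i] <- b
    names[i] <- if (length(tok) >= 9)
      paste(tok[9:length(tok)], collapse = " ") else paste0("ch", i)
  }
  if (length(unique(datf)) != 1L)
    stop("multi-file WFDB records are not supported")
  dat <- file.path(dirname(base), datf[1])
  raw <- readBin(dat, "integer", n = k * n, size = 2L, endian = "little",
                 signed = TRUE)
  adc <- matrix(raw, ncol = k, byrow = TRUE)
  mv <- sweep(adc, 2L, baselines) %*% diag(1 / gains, k)
  MultichannelRecord(mv, fs, names, basename(base))
}

# MIT annotation format: sequence of little-endian 16-bit words; the high
# 6 bits carry the annotation code, the low 10 bits the time increment in
# samples.  Code 59 (SKIP) is followed by a 4-byte interval (high word
# first); a zero word terminates the stream.  Beats are written as code 1
# (NORMAL).
wfdbWriteAnnotations <- function(ann, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  prev <- 0L
  for (p in ann@peaks) {
    delta <- p - prev
    prev <- p
    if (delta >= 1024) {
      writeBin(as.integer(59L * 1024L), con, size = 2L, endian = "little")
      writeBin(as.integer(delta %/% 65536L), con, size = 2L, endian = "little")
      writeBin(as.integer(delta %% 65536L), con, size = 2L, endian = "little")
      delta <- 0L
    }
    writeBin(as.integer(1L * 1024L + delta), con, size = 2L, endian = "little")
  }
  writeBin(0L, con, size = 2L, endian = "little")
  invisible(path)
}

wfdbReadAnnotations <- function(path, fs, label = "reference") {
  raw <- readBin(path, "integer", n = file.size(path) %/% 2L, size = 2L,
                 endian = "little", signed = FALSE)
  t <- 0L; peaks <- integer()
  i <- 1L
  while (i <= length(raw)) {
    word <- raw[i]
    if (word == 0L) break
    code <- word %/% 1024L
    delta <- word %% 1024L
    if (code == 59L) {  # SKIP: long interval in the next two words
      t <- t + raw[i + 1L] * 65536L + raw[i + 2L]
      i <- i + 3L
      next
    }
    t <- t + delta
    if (code >= 1L && code <= 49L) peaks <- c(peaks, t)  # beat annotations
    i <- i + 1L
  }
  BeatAnnotations(peaks, fs, label)
}
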