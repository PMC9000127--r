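# Grid-search optimization of the adaptive control parameters on the F1
# objective: per-cell evaluation, row-major (resumable) search over a
# two-parameter grid, global-maximum selection with tie reporting, and
# surface export/plotting.

#' Parameter grid for adaptive-filter optimization
#'
#' Axis 1 is the continuous control parameter (`mu` for LMS/Sign-Error
#' LMS, `lam` for RLS/FTF, `eta` for ADALINE); axis 2 is the filter
#' length (`M`, or input space `p` for ADALINE).  Defaults: `mu`/`eta`
#' log-spaced over \[1e-3, 0.1\] (25 points), `lam` linear over
#' \[0.98, 1\] (21 points), `M`/`p` in \{1, 5, 10, ..., 100\}; `fine = TRUE`
#' steps `M` by 1 and `mu`/`eta` by 0.001 for interval-style reporting of
#' optimum plateaus.
#'
#' @param algorithm adaptive algorithm name.
#' @param axis1,axis2 optional explicit axis value vectors.
#' @param fine use the dense grid.
#' @return a list of class `"ParamGrid"` with `axis1Name`, `axis1`,
#'   `axis2Name`, `axis2`.
#' @export
paramGrid <- function(algorithm = c("lms", "selms", "adaline", "rls", "ftf"),
                      axis1 = NULL, axis2 = NULL, fine = FALSE) {
  algorithm <- match.arg(algorithm)
  axis1Name <- switch(algorithm, lms = "mu", selms = "mu", adaline = "eta",
                      rls = "lam", ftf = "lam")
  axis2Name <- if (algorithm == "adaline") "p" else "M"
  if (is.null(axis1)) {
    axis1 <- if (axis1Name == "lam") seq(0.98, 1.0, length.out = 21)
    else if (fine) seq(0.001, 0.1, by = 0.001)
    else pmin(exp(seq(log(1e-3), log(0.1), length.out = 25)), 0.1)
  }
  if (is.null(axis2)) {
    axis2 <- if (fine) 1:100 else c(1, seq(5, 100, by = 5))
  }
  if (axis1Name == "lam") {
    if (any(axis1 < 0.9 | axis1 > 1)) stop("lam values must lie in [0.9, 1]")
  } else if (any(axis1 <= 0 | axis1 > 0.1)) {
    stop(axis1Name, " values must lie in (0, 0.1]")
  }
  if (any(axis2 < 1 | axis2 > 100 | axis2 != round(axis2)))
    stop(axis2Name, " values must be integers in [1, 100]")
  structure(list(algorithm = algorithm, axis1Name = axis1Name,
                 axis1 = as.numeric(axis1), axis2Name = axis2Name,
                 axis2 = as.numeric(axis2)),
            class = "ParamGrid")
}

.cellConfig <- function(algorithm, v1, v2, base = NULL) {
  args <- list(algorithm = algorithm)
  if (algorithm %in% c("lms", "selms")) { args$mu <- v1; args$M <- v2 }
  else if (algorithm == "adaline") { args$eta <- v1; args$p <- v2 }
  else { args$lam <- v1; args$M <- v2 }
  if (!is.null(base))
    for (nm in setdiff(names(base), names(args))) args[[nm]] <- base[[nm]]
  do.call(adaptiveConfig, args)
}

#' Evaluate one grid cell
#'
#' Runs adaptive cancellation with the cell's parameters, detects fetal
#' R-peaks on the error signal, and scores them against the reference in
#' 1-minute windows; returns the micro-averaged F1.  Failed filter runs
#' (divergence, FTF instability) are recorded as failed cells, not
#' raised.
#'
#' @param algorithm adaptive algorithm name.
#' @param v1,v2 axis-1 (mu/lam/eta) and axis-2 (M/p) values.
#' @param primary,reference primary (aECG*) and reference (mECG*) signals.
#' @param referenceAnnotations reference fetal beats
#'   ([BeatAnnotations-class]).
#' @param fs sampling rate, Hz.
#' @param detector a [detectorConfig()].
#' @param windowS,toleranceMs evaluation window and matching tolerance.
#' @param adaptiveDefaults named list of extra [adaptiveConfig()] fields
#'   (e.g. `initDelta`).
#' @return list with `f1`, `tp`, `fp`, `fn`, `failed`.
#' @export
evaluateCell <- function(algorithm, v1, v2, primary, reference,
                         referenceAnnotations, fs,
                         detector = detectorConfig(), windowS = 60,
                         toleranceMs = 50, adaptiveDefaults = NULL) {
  cfg <- .cellConfig(algorithm, v1, v2, adaptiveDefaults)
  run <- tryCatch(runAdaptive(cfg, primary, reference),
                  error = function(e) NULL)
  if (is.null(run))
    return(list(f1 = NA_real_, tp = NA_integer_, fp = NA_integer_,
                fn = NA_integer_, failed = TRUE))
  det <- detectFQRS(run@fecgEst, fs, detector)
  rep <- windowedCounts(det, referenceAnnotations, windowS, toleranceMs)
  list(f1 = f1(rep@tp, rep@fp, rep@fn), tp = rep@tp, fp = rep@fp,
       fn = rep@fn, failed = FALSE)
}

#' Grid search of the F1 surface
#'
#' Evaluates every cell of the grid row-major (axis 1 outer).  With a
#' `checkpoint` path the per-row state is saved and a restarted search
#' resumes where it stopped, yielding a surface identical to a fresh run.
#'
#' @inheritParams evaluateCell
#' @param grid a [paramGrid()].
#' @param checkpoint optional path for resumable state.
#' @param verbose print per-row progress.
#' @return an [OptimizationSurface-class].
#' @seealso [findOptimum()], [exportSurface()]
#' @export
gridSearch <- function(grid, primary, reference, referenceAnnotations, fs,
                       detector = detectorConfig(), windowS = 60,
                       toleranceMs = 50, adaptiveDefaults = NULL,
                       checkpoint = NULL, verbose = FALSE) {
  stopifnot(inherits(grid, "ParamGrid"))
  n1 <- length(grid$axis1); n2 <- length(grid$axis2)
  f1m <- matrix(NA_real_, n1, n2)
  tpm <- fpm <- fnm <- matrix(NA_integer_, n1, n2)
  flm <- matrix(FALSE, n1, n2)
  start <- 1L
  if (!is.null(checkpoint) && file.exists(checkpoint)) {
    st <- readRDS(checkpoint)
    if (identical(st$grid, grid[c("algorithm", "axis1", "axis2")])) {
      f1m <- st$f1; tpm <- st$tp; fpm <- st$fp; fnm <- st$fn; flm <- st$failed
      start <- st$nextRow
    }
  }
  if (start <= n1) for (i in start:n1) {
    for (j in seq_len(n2)) {
      cell <- evaluateCell(grid$algorithm, grid$axis1[i], grid$axis2[j],
                           primary, reference, referenceAnnotations, fs,
                           detector, windowS, toleranceMs, adaptiveDefaults)
      f1m[i, j] <- cell$f1; tpm[i, j] <- cell$tp
      fpm[i, j] <- cell$fp; fnm[i, j] <- cell$fn
      flm[i, j] <- cell$failed
    }
    if (verbose)
      message(sprintf("row %d/%d (%s = %g): best F1 so far %.2f%%",
                      i, n1, grid$axis1Name, grid$axis1[i],
                      suppressWarnings(max(f1m, na.rm = TRUE))))
    if (!is.null(checkpoint))
      saveRDS(list(grid = grid[c("algorithm", "axis1", "axis2")],
                   f1 = f1m, tp = tpm, fp = fpm, fn = fnm, failed = flm,
                   nextRow = i + 1L),
              checkpoint)
  }
  new("OptimizationSurface", algorithm = grid$algorithm,
      axis1Name = grid$axis1Name, axis2Name = grid$axis2Name,
      axis1 = grid$axis1, axis2 = grid$axis2,
      f1 = f1m, tp = tpm, fp = fpm, fn = fnm, failed = flm)
}

#' Locate the global maximum of an optimization surface
#'
#' The optimum is the maximal F1 over non-failed cells.  Cells whose F1
#' ties the maximum within 1e-9 form the reported tie set (optimum
#' plateaus appear as parameter intervals); the canonical representative
#' is the tie with the smallest filter length, then the axis-1 value
#' toward stability (smallest `mu`/`eta`, largest `lam`).
#'
#' @param surface an [OptimizationSurface-class].
#' @return list with `params` (named axis values), `f1`, and `ties`
#'   (data.frame of all tied cells).
#' @export
findOptimum <- function(surface) {
  stopifnot(is(surface, "OptimizationSurface"))
  vals <- surface@f1
  vals[surface@failed] <- NA_real_
  if (all(is.na(vals))) stop("all grid cells failed; no optimum exists")
  top <- max(vals, na.rm = TRUE)
  idx <- which(!is.na(vals) & abs(vals - top) <= 1e-9, arr.ind = TRUE)
  ties <- data.frame(a1 = surface@axis1[idx[, 1]],
                     a2 = surface@axis2[idx[, 2]],
                     f1 = vals[idx])
  names(ties)[1:2] <- c(surface@axis1Name, surface@axis2Name)
  a1dir <- if (surface@axis1Name == "lam") -1 else 1   # largest lam wins
  ord <- order(ties[[2]], a1dir * ties[[1]])
  ties <- ties[ord, , drop = FALSE]
  rownames(ties) <- NULL
  params <- c(ties[1, 1], ties[1, 2])
  names(params) <- c(surface@axis1Name, surface@axis2Name)
  list(params = params, f1 = ties$f1[1], ties = ties)
}

#' Export / import an optimization surface
#'
#' `"json"` serializes the full surface losslessly; `"csv"` writes the
#' long-format grid (axis1, axis2, f1, tp, fp, fn, failed) with the axis
#' names in the header.  [readSurface()] reconstructs the object from
#' either format.
#'
#' @param surface an [OptimizationSurface-class].
#' @param path output path.
#' @param format `"auto"` (by extension), `"json"`, or `"csv"`.
#' @return `path`, invisibly.
#' @export
exportSurface <- function(surface, path, format = c("auto", "json", "csv")) {
  stopifnot(is(surface, "OptimizationSurface"))
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "json"
  if (format == "json") {
    obj <- list(schema = "nifECG-surface-1", algorithm = surface@algorithm,
                axis1_name = surface@axis1Name,
                axis2_name = surface@axis2Name,
                axis1 = surface@axis1, axis2 = surface@axis2,
                f1 = surface@f1, tp = surface@tp, fp = surface@fp,
                fn = surface@fn, failed = surface@failed)
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         na = "null", matrix = "rowmajor")
  } else {
    g <- expand.grid(j = seq_along(surface@axis2),
                     i = seq_along(surface@axis1))
    df <- data.frame(surface@axis1[g$i], surface@axis2[g$j],
                     algorithm = surface@algorithm,
                     f1 = surface@f1[cbind(g$i, g$j)],
                     tp = surface@tp[cbind(g$i, g$j)],
                     fp = surface@fp[cbind(g$i, g$j)],
                     fn = surface@fn[cbind(g$i, g$j)],
                     failed = surface@failed[cbind(g$i, g$j)])
    names(df)[1:2] <- c(surface@axis1Name, surface@axis2Name)
    utils::write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname exportSurface
#' @export
readSurface <- function(path, format = c("auto", "json", "csv")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "json"
  if (format == "json") {
    o <- jsonlite::fromJSON(path)
    asm <- function(m, mode) { m <- as.matrix(m); storage.mode(m) <- mode; m }
    return(new("OptimizationSurface", algorithm = o$algorithm,
               axis1Name = o$axis1_name, axis2Name = o$axis2_name,
               axis1 = as.numeric(o$axis1), axis2 = as.numeric(o$axis2),
               f1 = asm(o$f1, "double"), tp = asm(o$tp, "integer"),
               fp = asm(o$fp, "integer"), fn = asm(o$fn, "integer"),
               failed = asm(o$failed, "logical")))
  }
  df <- utils::read.csv(path)
  axis1Name <- names(df)[1]; axis2Name <- names(df)[2]
  a1 <- sort(unique(df[[1]])); a2 <- sort(unique(df[[2]]))
  i <- match(df[[1]], a1); j <- match(df[[2]], a2)
  mk <- function(col, mode) {
    m <- matrix(if (mode == "double") NA_real_ else NA_integer_,
                length(a1), length(a2))
    m[cbind(i, j)] <- df[[col]]
    storage.mode(m) <- mode
    m
  }
  fl <- matrix(FALSE, length(a1), length(a2))
  fl[cbind(i, j)] <- as.logical(df$failed)
  new("OptimizationSurface", algorithm = df$algorithm[1],
      axis1Name = axis1Name, axis2Name = axis2Name,
      axis1 = a1, axis2 = a2, f1 = mk("f1", "double"),
      tp = mk("tp", "integer"), fp = mk("fp", "integer"),
      fn = mk("fn", "integer"), failed = fl)
}

#' Map F1 values to color indices
#'
#' Monotone linear mapping of F1 (percent) onto `1..n` color indices, as
#' used by [plotSurface()]: a higher F1 never maps to a lower index.
#'
#' @param f1 numeric F1 values (NA allowed).
#' @param n number of colors.
#' @return integer indices in `1..n` (NA preserved).
#' @export
f1ColorIndex <- function(f1, n = 256L) {
  idx <- 1L + as.integer(floor(pmin(pmax(f1, 0), 100) / 100 * (n - 1L)))
  idx[is.na(f1)] <- NA_integer_
  idx
}

#' Plot an optimization surface
#'
#' Heatmap of the F1 grid (failed cells blank), the package's rendering of
#' the 3D optimization graphs.
#'
#' @param surface an [OptimizationSurface-class].
#' @param ... passed to [graphics::image()].
#' @return invisibly, the color index matrix.
#' @export
plotSurface <- function(surface, ...) {
  stopifnot(is(surface, "OptimizationSurface"))
  vals <- surface@f1
  vals[surface@failed] <- NA_real_
  pal <- grDevices::hcl.colors(256, "YlOrRd", rev = TRUE)
  graphics::image(surface@axis1, surface@axis2, vals, col = pal,
                  zlim = c(0, 100), xlab = surface@axis1Name,
                  ylab = surface@axis2Name,
                  main = paste("F1 surface:", surface@algorithm), ...)
  invisible(matrix(f1ColorIndex(vals), nrow(vals), ncol(vals)))
}
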