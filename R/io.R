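#' Read and write grayscale image stacks as multi-page TIFF
#'
#' `writeStackTIFF()` writes a height x width x frames numeric array as a
#' multi-page grayscale TIFF; intensities are scaled by `maxIntensity`
#' (255 for 8-bit-range data) into the unit range the TIFF writer expects
#' and clipped to `[0, 1]`. `readStackTIFF()` reads such a file back into
#' an array on the original intensity scale.
#'
#' @param stack numeric array, height x width x frames.
#' @param file path to the TIFF file.
#' @param maxIntensity intensity corresponding to full scale.
#' @param bitsPerSample 8 or 16.
#' @return `writeStackTIFF()` returns `file` invisibly; `readStackTIFF()`
#'   returns the stack array.
#' @name stackTIFF
NULL

#' @rdname stackTIFF
#' @export
writeStackTIFF <- function(stack, file, maxIntensity = 255,
                           bitsPerSample = 16) {
  stopIfNot(is.array(stack) && length(dim(stack)) == 3L,
            "stack must be a height x width x frames array")
  n <- dim(stack)[3L]
  pages <- lapply(seq_len(n), function(t)
    pmin(1, pmax(0, stack[, , t] / maxIntensity)))
  tiff::writeTIFF(pages, file, bits.per.sample = bitsPerSample)
  invisible(file)
}

#' @rdname stackTIFF
#' @export
readStackTIFF <- function(file, maxIntensity = 255) {
  pages <- tiff::readTIFF(file, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1L]  # collapse channels
    p * maxIntensity
  })
  array(unlist(pages), dim = c(dim(pages[[1L]]), length(pages)))
}

#' Write / read bout tables and trace tables as CSV
#'
#' Plain-text interchange for the package's tabular outputs: bout tables
#' (`kind`, `start_s`, `end_s`, `duration_s`, `at_edge`), activity traces
#' (`frame`, `time_s`, `changed_pixels`, `active`) and fluorescence traces
#' (`frame`, `time_s`, `gcamp`, `rfp`).
#'
#' @param series a [BoutSeries-class] (`writeBoutTable`) or
#'   [ActivityTrace-class] (`writeActivityTable`).
#' @param traces data.frame with `gcamp`/`rfp` columns
#'   (`writeTraceTable`), e.g. from [simulateCalcium()].
#' @param file path to the CSV file.
#' @return the file path, invisibly.
#' @name tableIO
NULL

#' @rdname tableIO
#' @export
writeBoutTable <- function(series, file) {
  stopIfNot(is(series, "BoutSeries"), "series must be a BoutSeries")
  b <- bouts(series)
  utils::write.csv(data.frame(
    kind = b$kind, start_s = b$start, end_s = b$end,
    duration_s = b$duration, at_edge = b$atEdge
  ), file, row.names = FALSE)
  invisible(file)
}

#' @rdname tableIO
#' @export
writeActivityTable <- function(series, file) {
  stopIfNot(is(series, "ActivityTrace"), "series must be an ActivityTrace")
  n <- length(series)
  utils::write.csv(data.frame(
    frame = seq_len(n),
    time_s = (seq_len(n) - 1L) / fps(series),
    changed_pixels = changedPixels(series),
    active = activeState(series)
  ), file, row.names = FALSE)
  invisible(file)
}

#' @rdname tableIO
#' @export
writeTraceTable <- function(traces, file) {
  stopIfNot(is.data.frame(traces) &&
              all(c("gcamp", "rfp") %in% names(traces)),
            "traces must have gcamp and rfp columns")
  keep <- intersect(c("frame", "time_s", "gcamp", "rfp"), names(traces))
  utils::write.csv(traces[keep], file, row.names = FALSE)
  invisible(file)
}

#' @rdname tableIO
#' @export
readTraceTable <- function(file) {
  utils::read.csv(file)
}
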