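#' Pair each sleep bout with its immediately preceding motion bout
#'
#' Sleep homeostasis predicts that longer motion bouts are followed by
#' longer sleep bouts. This builds the (prior motion duration, sleep
#' duration) pairs from a segmented series: every sleep bout immediately
#' preceded by a motion bout yields one pair, in order. With `dropEdges`
#' (the conservative default) pairs in which either bout touches a
#' recording boundary are excluded, since truncated durations are not
#' interpretable.
#'
#' @param series a [BoutSeries-class] (typically segmented within a
#'   detected lethargus interval).
#' @param dropEdges exclude pairs involving edge-truncated bouts.
#' @return data.frame with columns `priorMotion` and `sleep` (seconds).
#' @export
pairSleepWithPriorMotion <- function(series, dropEdges = TRUE) {
  stopIfNot(is(series, "BoutSeries"), "series must be a BoutSeries")
  b <- bouts(series)
  idx <- which(b$kind == "sleep")
  idx <- idx[idx > 1L]
  if (length(idx))
    idx <- idx[b$kind[idx - 1L] == "motion"]
  if (dropEdges && length(idx))
    idx <- idx[!b$atEdge[idx] & !b$atEdge[idx - 1L]]
  if (!length(idx))
    stop("no (motion, sleep) pair available", call. = FALSE)
  data.frame(priorMotion = b$duration[idx - 1L], sleep = b$duration[idx])
}

#' Compare sleep-bout durations binned by prior motion-bout duration
#'
#' Groups sleep durations by bins of the preceding motion-bout duration
#' (default: two bins split at the pooled median) and tests whether sleep
#' duration differs across bins -- the signature of sleep homeostasis.
#' With a single genotype the across-bin comparison is a Welch t test (two
#' bins) or one-way ANOVA (more bins). With a `genotype` column present (or
#' supplied), a two-way ANOVA with a genotype x bin interaction is fitted,
#' plus per-bin between-genotype Welch t tests with Sidak correction.
#'
#' @param pairs data.frame from [pairSleepWithPriorMotion()], optionally
#'   with a `genotype` column.
#' @param binEdges numeric vector of interior bin edges on prior motion
#'   duration (seconds); `NULL` splits at the pooled median.
#' @param genotype optional vector of genotype labels, one per pair.
#' @return list with `table` (per bin x genotype: n, mean, sem),
#'   `acrossBinP` (p-value(s) of the across-bin comparison, named by
#'   genotype), and, when several genotypes are present, `interactionP`
#'   and `pairwise` (per-bin genotype contrasts, Sidak-adjusted).
#'   Empty bins are reported in `emptyBins` and excluded from contrasts.
#' @export
binnedHomeostasisTest <- function(pairs, binEdges = NULL, genotype = NULL) {
  stopIfNot(is.data.frame(pairs) &&
              all(c("priorMotion", "sleep") %in% names(pairs)),
            "pairs must have priorMotion and sleep columns")
  if (is.null(genotype))
    genotype <- if ("genotype" %in% names(pairs)) pairs$genotype
                else rep("pooled", nrow(pairs))
  stopIfNot(length(genotype) == nrow(pairs),
            "genotype must have one label per pair")

  if (is.null(binEdges))
    binEdges <- stats::median(pairs$priorMotion)
  breaks <- c(-Inf, sort(binEdges), Inf)
  bin <- cut(pairs$priorMotion, breaks = breaks, right = FALSE)
  stopIfNot(nlevels(bin) >= 2L, "at least 2 bins required")

  d <- data.frame(sleep = pairs$sleep, bin = bin,
                  genotype = factor(genotype))
  empty <- levels(bin)[!(levels(bin) %in% unique(as.character(d$bin)))]
  d$bin <- droplevels(d$bin)
  if (nlevels(d$bin) < 2L)
    stop("fewer than 2 non-empty bins", call. = FALSE)

  agg <- do.call(rbind, lapply(split(d, list(d$genotype, d$bin),
                                     drop = TRUE), function(g) {
    data.frame(genotype = g$genotype[1L], bin = g$bin[1L],
               n = nrow(g), mean = mean(g$sleep),
               sem = stats::sd(g$sleep) / sqrt(nrow(g)))
  }))
  rownames(agg) <- NULL

  acrossBinP <- vapply(split(d, d$genotype), function(g) {
    g$bin <- droplevels(g$bin)
    if (nlevels(g$bin) < 2L) return(NA_real_)
    if (nlevels(g$bin) == 2L) {
      tryCatch(stats::t.test(sleep ~ bin, data = g)$p.value,
               error = function(e) NA_real_)  # zero-variance bins
    } else {
      stats::anova(stats::lm(sleep ~ bin, data = g))[["Pr(>F)"]][1L]
    }
  }, numeric(1L))

  out <- list(table = agg, acrossBinP = acrossBinP, emptyBins = empty)

  if (nlevels(d$genotype) >= 2L) {
    fit <- stats::aov(sleep ~ genotype * bin, data = d)
    tab <- summary(fit)[[1L]]
    rn <- trimws(rownames(tab))
    out$interactionP <- tab[["Pr(>F)"]][rn == "genotype:bin"]
    pw <- do.call(rbind, lapply(split(d, d$bin), function(g) {
      if (length(unique(g$genotype)) < 2L) return(NULL)
      gl <- levels(droplevels(g$genotype))
      data.frame(bin = g$bin[1L],
                 contrast = paste(gl[1L], "vs", gl[2L]),
                 p = stats::t.test(sleep ~ droplevels(genotype),
                                   data = g)$p.value)
    }))
    if (!is.null(pw)) {
      pw$pAdjSidak <- sidakAdjust(pw$p)
      rownames(pw) <- NULL
    }
    out$pairwise <- pw
  }
  out
}

#' Summarize sleep architecture within and outside lethargus
#'
#' Computes the mean motion- and sleep-bout durations and transition count
#' over the bouts lying fully inside the lethargus interval, the lethargus
#' length, and the mean fraction of quiescence inside versus outside
#' lethargus. The transition count is the number of bout boundaries
#' strictly inside the interval. When no lethargus interval is supplied
#' (not detected), the summary covers the whole recording and is flagged.
#'
#' @param series a [BoutSeries-class].
#' @param lethargus list with `start`/`end` from [detectLethargus()], or
#'   `NULL`.
#' @param q optional quiescence table from [fractionOfQuiescence()], used
#'   for the inside/outside fraction-of-quiescence means.
#' @return list with `meanMotionDuration`, `meanSleepDuration`,
#'   `lethargusLength`, `transitionCount`, `fractionQuiescenceIn`,
#'   `fractionQuiescenceOut`, and `wholeRecording` (flag).
#' @export
summarizeArchitecture <- function(series, lethargus = NULL, q = NULL) {
  stopIfNot(is(series, "BoutSeries"), "series must be a BoutSeries")
  b <- bouts(series)
  whole <- is.null(lethargus)
  if (whole) lethargus <- list(start = 0, end = totalDuration(series))
  stopIfNot(lethargus$start >= 0 &&
              lethargus$end <= totalDuration(series) + 1e-8,
            "lethargus interval must lie within the recording")

  tol <- 1e-8
  inside <- b$start >= lethargus$start - tol & b$end <= lethargus$end + tol
  bi <- b[inside, , drop = FALSE]
  boundaries <- b$end[-nrow(b)]
  transitionCount <- sum(boundaries > lethargus$start + tol &
                           boundaries < lethargus$end - tol)

  fracIn <- fracOut <- NA_real_
  if (!is.null(q)) {
    winIn <- q$window_start_s >= lethargus$start - tol &
      q$window_start_s < lethargus$end - tol
    if (any(winIn))
      fracIn <- stats::weighted.mean(q$fraction[winIn], q$n_frames[winIn])
    if (any(!winIn))
      fracOut <- stats::weighted.mean(q$fraction[!winIn],
                                      q$n_frames[!winIn])
  }

  list(
    meanMotionDuration = mean(bi$duration[bi$kind == "motion"]),
    meanSleepDuration = mean(bi$duration[bi$kind == "sleep"]),
    lethargusLength = lethargus$end - lethargus$start,
    transitionCount = transitionCount,
    fractionQuiescenceIn = fracIn,
    fractionQuiescenceOut = fracOut,
    wholeRecording = whole
  )
}
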