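#' Extract per-bout trace segments
#'
#' Cuts a per-frame trace into the frame segments belonging to each bout of
#' a bout table (typically the output of [filterBouts()]), aligned at the
#' bout start on the native frame grid.
#'
#' @param trace numeric vector (e.g. `drOverR0(x)` or changed-pixel
#'   counts), one value per frame.
#' @param boutTable data.frame with `start`/`end` columns in seconds (a
#'   [BoutSeries-class] is also accepted, in which case all its bouts are
#'   used).
#' @param fps frames per second of `trace`.
#' @param kind optionally restrict to `"sleep"` or `"motion"` bouts.
#' @return named list of numeric vectors, one per bout.
#' @export
boutSegments <- function(trace, boutTable, fps, kind = NULL) {
  if (is(boutTable, "BoutSeries")) boutTable <- bouts(boutTable)
  stopIfNot(is.data.frame(boutTable) &&
              all(c("start", "end") %in% names(boutTable)),
            "boutTable must have start and end columns")
  if (!is.null(kind) && "kind" %in% names(boutTable)) {
    kind <- match.arg(kind, c("sleep", "motion"))
    boutTable <- boutTable[boutTable$kind == kind, , drop = FALSE]
  }
  n <- length(trace)
  segs <- lapply(seq_len(nrow(boutTable)), function(i) {
    i0 <- as.integer(round(boutTable$start[i] * fps)) + 1L
    i1 <- min(n, as.integer(round(boutTable$end[i] * fps)))
    trace[i0:i1]
  })
  names(segs) <- paste0("bout", seq_along(segs))
  segs
}

#' Bout-aligned average with SEM and sample counts
#'
#' Aligns per-bout trace segments at the bout start on the native frame
#' grid and computes, per time point, the mean, SEM and number of
#' contributing bouts. Time points to which `minSamples` or fewer bouts
#' contribute are omitted (strict: a count equal to `minSamples` is
#' dropped). SEM is reported only where at least two bouts contribute.
#'
#' @param segments list of numeric vectors from [boutSegments()].
#' @param fps frames per second.
#' @param minSamples omission threshold on the per-time-point count.
#' @return data.frame with columns `time_s`, `mean`, `sem`, `n`.
#' @export
alignAndAverage <- function(segments, fps, minSamples = 10) {
  stopIfNot(is.list(segments) && length(segments) > 0,
            "segments must be a non-empty list")
  stopIfNot(fps > 0, "fps must be positive")
  lens <- lengths(segments)
  maxLen <- max(lens)
  mat <- matrix(NA_real_, nrow = length(segments), ncol = maxLen)
  for (i in seq_along(segments)) mat[i, seq_len(lens[i])] <- segments[[i]]

  n <- as.integer(colSums(!is.na(mat)))
  mu <- colMeans(mat, na.rm = TRUE)
  sem <- apply(mat, 2L, function(col) {
    col <- col[!is.na(col)]
    if (length(col) >= 2L) stats::sd(col) / sqrt(length(col)) else NA_real_
  })
  keep <- n > minSamples
  data.frame(
    time_s = (which(keep) - 1L) / fps,
    mean = mu[keep], sem = sem[keep], n = n[keep]
  )
}

#' Duration-normalized bout profile with quartile means
#'
#' Normalizes the duration of each bout to 1, linearly resamples its trace
#' onto a fixed grid over `[0, 1]`, and averages across bouts. The grid
#' points sit at bin midpoints `(i - 0.5)/gridSize`, so quartile means of
#' smooth signals match their continuous closed forms. Per bout, the means
#' over the first (`[0, 0.25)`) and fourth (`[0.75, 1]`) quarters of
#' normalized time are returned for a paired first-vs-last-quarter test.
#' Bouts shorter than 2 frames are skipped with a warning.
#'
#' @param segments list of numeric vectors from [boutSegments()].
#' @param gridSize number of grid points over normalized time.
#' @return list with `profile` (data.frame `grid`, `mean`, `sem`) and
#'   `perBout` (data.frame `bout`, `q1`, `q4`).
#' @export
normalizedProfile <- function(segments, gridSize = 100) {
  stopIfNot(is.list(segments) && length(segments) > 0,
            "segments must be a non-empty list")
  stopIfNot(gridSize >= 4, "gridSize must be at least 4")
  short <- lengths(segments) < 2L
  if (any(short)) {
    warning(sum(short), " bout(s) shorter than 2 frames skipped")
    segments <- segments[!short]
  }
  stopIfNot(length(segments) > 0, "no bout with at least 2 frames")

  grid <- (seq_len(gridSize) - 0.5) / gridSize
  res <- vapply(segments, function(seg) {
    x <- seq(0, 1, length.out = length(seg))
    stats::approx(x, seg, xout = grid)$y
  }, numeric(gridSize))
  res <- matrix(res, nrow = gridSize)

  inQ1 <- grid < 0.25
  inQ4 <- grid >= 0.75
  perBout <- data.frame(
    bout = seq_len(ncol(res)),
    q1 = colMeans(res[inQ1, , drop = FALSE]),
    q4 = colMeans(res[inQ4, , drop = FALSE])
  )
  nB <- ncol(res)
  profile <- data.frame(
    grid = grid,
    mean = rowMeans(res),
    sem = if (nB >= 2L) apply(res, 1L, stats::sd) / sqrt(nB)
          else rep(NA_real_, gridSize)
  )
  list(profile = profile, perBout = perBout)
}

#' Transition-triggered pre/post window means
#'
#' For each sleep-to-motion (SM) or motion-to-sleep (MS) transition whose
#' flanking bouts both last at least `window` seconds, computes the mean of
#' the trace over the `window` seconds before and after the transition
#' (both windows lie fully inside the flanking bouts). Events lacking full
#' windows are excluded and their count attached as attribute
#' `n_excluded`.
#'
#' @param trace numeric vector, one value per frame.
#' @param series a [BoutSeries-class].
#' @param kind `"SM"` or `"MS"`.
#' @param window window length in seconds (12 by the imaging analysis).
#' @param dropEdges exclude transitions whose flanking bouts touch the
#'   recording boundaries.
#' @return data.frame with columns `time_s` (transition time), `preMean`,
#'   `postMean`, one row per event.
#' @export
transitionTriggered <- function(trace, series, kind = c("MS", "SM"),
                                window = 12, dropEdges = TRUE) {
  kind <- match.arg(kind)
  stopIfNot(is(series, "BoutSeries"), "series must be a BoutSeries")
  stopIfNot(window > 0, "window must be positive")
  b <- bouts(series)
  fr <- fps(series)
  wFrames <- as.integer(round(window * fr))
  n <- length(trace)

  fromKind <- if (kind == "MS") "motion" else "sleep"
  toKind <- if (kind == "MS") "sleep" else "motion"

  rows <- list()
  nExcluded <- 0L
  for (i in seq_len(nrow(b) - 1L)) {
    if (b$kind[i] != fromKind || b$kind[i + 1L] != toKind) next
    ok <- b$duration[i] >= window && b$duration[i + 1L] >= window &&
      (!dropEdges || (!b$atEdge[i] && !b$atEdge[i + 1L]))
    tf <- as.integer(round(b$end[i] * fr))  # last frame of the pre bout
    ok <- ok && (tf - wFrames + 1L >= 1L) && (tf + wFrames <= n)
    if (!ok) {
      nExcluded <- nExcluded + 1L
      next
    }
    pre <- trace[(tf - wFrames + 1L):tf]
    post <- trace[(tf + 1L):(tf + wFrames)]
    rows[[length(rows) + 1L]] <- data.frame(
      time_s = b$end[i],
      preMean = mean(pre, na.rm = TRUE),
      postMean = mean(post, na.rm = TRUE)
    )
  }
  if (!length(rows))
    stop("no qualifying ", kind, " transitions", call. = FALSE)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "n_excluded") <- nExcluded
  out
}

#' Peak latency versus peak intensity within motion bouts
#'
#' Smooths each bout's trace with a centered 1-s moving average (truncated
#' edges), finds the peak value and its latency from the bout start (first
#' occurrence on ties), and regresses peak value on latency by ordinary
#' least squares, reporting the Pearson correlation and a 95% confidence
#' band of the fitted line.
#'
#' @param segments list of per-bout trace vectors (motion bouts passing the
#'   12-s filter; see [boutSegments()]).
#' @param fps frames per second.
#' @param smooth moving-average width in seconds.
#' @return list with `peaks` (data.frame `bout`, `peak`, `latency_s`) and,
#'   when at least 3 bouts with non-degenerate variance exist,
#'   `slope`, `intercept`, `r`, `p`, and `fit` (the `lm` object; use
#'   `predict(fit, interval = "confidence")` for the 95% band). With fewer
#'   bouts or zero variance the regression fields are `NA` and `fit` is
#'   `NULL`.
#' @export
peakLatencyCorrelation <- function(segments, fps, smooth = 1) {
  stopIfNot(is.list(segments) && length(segments) > 0,
            "segments must be a non-empty list")
  stopIfNot(fps > 0, "fps must be positive")

  peaks <- do.call(rbind, lapply(seq_along(segments), function(i) {
    sm <- movingAverage(segments[[i]], smooth, fps)
    j <- which.max(sm)  # first occurrence on ties
    data.frame(bout = i, peak = sm[j], latency_s = (j - 1L) / fps)
  }))
  rownames(peaks) <- NULL

  out <- list(peaks = peaks, slope = NA_real_, intercept = NA_real_,
              r = NA_real_, p = NA_real_, fit = NULL)
  if (nrow(peaks) >= 3L &&
      stats::var(peaks$latency_s) > 0 && stats::var(peaks$peak) > 0) {
    fit <- stats::lm(peak ~ latency_s, data = peaks)
    ct <- stats::cor.test(peaks$latency_s, peaks$peak, method = "pearson")
    out$slope <- unname(stats::coef(fit)[2L])
    out$intercept <- unname(stats::coef(fit)[1L])
    out$r <- unname(ct$estimate)
    out$p <- ct$p.value
    out$fit <- fit
  }
  out
}

#' Cumulative locomotor activity within motion bouts
#'
#' Computes the running sum of locomotor activity (changed-pixel counts)
#' from the start of each motion bout, with a linearity diagnostic (R^2 of
#' a straight-line fit of the cumulative curve against time) per bout. A
#' near-1 R^2 indicates an essentially constant locomotor rate across the
#' bout.
#'
#' @param changed numeric vector of per-frame locomotor activity, or an
#'   [ActivityTrace-class].
#' @param boutTable data.frame of motion bouts (or a [BoutSeries-class],
#'   in which case its motion bouts are used).
#' @param fps frames per second (taken from the trace when one is given).
#' @return list with `curves` (list of data.frames `time_s`, `cumulative`)
#'   and `r2` (numeric vector, one per bout; `NA` for degenerate bouts).
#' @export
cumulativeLocomotor <- function(changed, boutTable, fps) {
  if (is(changed, "ActivityTrace")) {
    fps <- fps(changed)
    changed <- changedPixels(changed)
  }
  if (is(boutTable, "BoutSeries")) {
    b <- bouts(boutTable)
    boutTable <- b[b$kind == "motion", , drop = FALSE]
  }
  segs <- boutSegments(changed, boutTable, fps)
  curves <- lapply(segs, function(seg) {
    data.frame(time_s = (seq_along(seg) - 1L) / fps,
               cumulative = cumsum(seg))
  })
  r2 <- vapply(curves, function(cv) {
    if (nrow(cv) < 3L || stats::var(cv$cumulative) == 0) return(NA_real_)
    ## perfect fits are expected for constant rates; silence the
    ## "essentially perfect fit" diagnostic
    suppressWarnings(
      summary(stats::lm(cumulative ~ time_s, data = cv))$r.squared)
  }, numeric(1L))
  list(curves = curves, r2 = unname(r2))
}
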