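#' Segment a binary activity trace into sleep and motion bouts
#'
#' A sleep bout is a maximal run of non-active frames whose duration
#' strictly exceeds `minSleepDuration` (6 s by the imaging/behaviour rule;
#' 5 s in the optogenetics protocol). All remaining frames -- active runs
#' and quiescent runs at or below the rule -- are merged into motion bouts,
#' so adjacent active segments separated only by a short quiescent run
#' coalesce. The output tiles `[0, totalDuration)` exactly with strictly
#' alternating kinds.
#'
#' @param active logical vector, per-frame locomotor state (`TRUE` =
#'   active), or an [ActivityTrace-class].
#' @param fps frames per second (taken from the trace when one is given).
#' @param minSleepDuration minimum sleep-bout duration in seconds (strict:
#'   a quiescent run of exactly this duration is classified as motion).
#' @return a [BoutSeries-class].
#'
#' @examples
#' act <- rep(c(TRUE, FALSE, TRUE), c(100, 80, 100))
#' segmentBouts(act, fps = 10)
#' @export
segmentBouts <- function(active, fps, minSleepDuration = 6) {
  if (is(active, "ActivityTrace")) {
    fps <- fps(active)
    active <- activeState(active)
  }
  stopIfNot(is.logical(active) && length(active) > 0,
            "active must be a non-empty logical vector")
  stopIfNot(fps > 0, "fps must be positive")
  stopIfNot(minSleepDuration >= 0, "minSleepDuration must be non-negative")

  r <- rle(active)
  isSleepRun <- !r$values & (r$lengths / fps > minSleepDuration)
  ## merge all non-sleep runs into motion bouts
  lab <- ifelse(isSleepRun, "sleep", "motion")
  keep <- c(TRUE, lab[-1L] != lab[-length(lab)])
  grp <- cumsum(keep)
  lens <- tapply(r$lengths, grp, sum)
  kinds <- lab[keep]

  endFrame <- cumsum(as.numeric(lens))
  startFrame <- c(0, endFrame[-length(endFrame)])
  n <- length(active)
  b <- data.frame(
    kind = kinds,
    start = startFrame / fps,
    end = endFrame / fps,
    stringsAsFactors = FALSE
  )
  b$duration <- b$end - b$start
  b$atEdge <- startFrame == 0 | endFrame == n
  rownames(b) <- NULL

  new("BoutSeries", bouts = b, fps = fps, totalDuration = n / fps,
      minSleepDuration = minSleepDuration)
}

#' Filter bouts by duration and edge status
#'
#' Returns the bouts whose duration strictly exceeds `minDuration`
#' (durations of exactly `minDuration` are dropped under the default strict
#' convention; set `inclusive = TRUE` to keep them) and, when `dropEdges`,
#' which do not touch the start or end of the recording. The input series
#' is left unmodified.
#'
#' @param series a [BoutSeries-class].
#' @param minDuration duration cutoff in seconds (12 by the imaging rule).
#' @param dropEdges drop bouts touching the recording boundaries.
#' @param kind optionally restrict to `"sleep"` or `"motion"` bouts.
#' @param inclusive keep bouts of exactly `minDuration`.
#' @return data.frame of retained bouts (same columns as `bouts(series)`).
#' @export
filterBouts <- function(series, minDuration = 12, dropEdges = TRUE,
                        kind = NULL, inclusive = FALSE) {
  stopIfNot(is(series, "BoutSeries"), "series must be a BoutSeries")
  b <- bouts(series)
  keep <- if (inclusive) b$duration >= minDuration
          else b$duration > minDuration
  if (dropEdges) keep <- keep & !b$atEdge
  if (!is.null(kind)) {
    kind <- match.arg(kind, c("sleep", "motion"))
    keep <- keep & b$kind == kind
  }
  out <- b[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Fraction of quiescence in non-overlapping time windows
#'
#' The fraction of quiescence is the ratio of non-locomotor-active frames
#' to all frames in each window. Windows are non-overlapping and anchored
#' at t = 0; a trailing partial window is reported with its own frame
#' count.
#'
#' @param active logical vector or [ActivityTrace-class].
#' @param fps frames per second (taken from the trace when one is given).
#' @param window window length in seconds (1.5 min for imaging, 10 min for
#'   plate behaviour).
#' @return data.frame with columns `window_start_s`, `n_frames`,
#'   `fraction`; the window length is attached as attribute `window`.
#' @export
fractionOfQuiescence <- function(active, fps, window) {
  if (is(active, "ActivityTrace")) {
    fps <- fps(active)
    active <- activeState(active)
  }
  stopIfNot(is.logical(active) && length(active) > 0,
            "active must be a non-empty logical vector")
  stopIfNot(fps > 0, "fps must be positive")
  winFrames <- as.integer(round(window * fps))
  stopIfNot(winFrames >= 1L, "window must be at least one frame long")

  n <- length(active)
  idx <- (seq_len(n) - 1L) %/% winFrames
  f <- factor(idx, levels = sort(unique(idx)))
  frac <- tapply(!active, f, mean)
  cnt <- tapply(active, f, length)
  out <- data.frame(
    window_start_s = sort(unique(idx)) * winFrames / fps,
    n_frames = as.integer(cnt),
    fraction = as.numeric(frac)
  )
  rownames(out) <- NULL
  attr(out, "window") <- window
  attr(out, "fps") <- fps
  out
}

#' Delimit lethargus in a long quiescence-fraction series
#'
#' Finds contiguous spans of windows whose quiescence fraction is at least
#' `enterThreshold`, extends each span outward while the fraction stays at
#' least `exitThreshold`, and returns the longest resulting span provided
#' it lasts at least `minSpan` seconds; otherwise `NULL`.
#'
#' @param q quiescence table from [fractionOfQuiescence()].
#' @param enterThreshold fraction needed to seed a lethargus span, in
#'   `[0, 1]`.
#' @param exitThreshold fraction needed to extend the span, in `[0, 1]`.
#' @param minSpan minimum span length in seconds (20 min default).
#' @return list with `start` and `end` (seconds), or `NULL` when no span
#'   qualifies.
#' @export
detectLethargus <- function(q, enterThreshold = 0.05,
                            exitThreshold = 0.05, minSpan = 1200) {
  stopIfNot(is.data.frame(q) && nrow(q) > 0, "q must be a non-empty table")
  stopIfNot(enterThreshold >= 0 && enterThreshold <= 1 &&
              exitThreshold >= 0 && exitThreshold <= 1,
            "thresholds must lie in [0, 1]")
  nw <- nrow(q)
  window <- attr(q, "window")
  if (is.null(window))
    window <- if (nw > 1L) q$window_start_s[2L] - q$window_start_s[1L]
              else q$n_frames[1L]
  fps <- attr(q, "fps")

  seedW <- q$fraction >= enterThreshold
  extW <- q$fraction >= exitThreshold
  if (!any(seedW)) return(NULL)

  ## contiguous spans of extendable windows that contain at least one seed
  r <- rle(extW)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  best <- NULL
  bestLen <- -1
  for (k in which(r$values)) {
    i0 <- starts[k]; i1 <- ends[k]
    if (!any(seedW[i0:i1])) next
    len <- i1 - i0 + 1L
    if (len > bestLen) {
      bestLen <- len
      best <- c(i0, i1)
    }
  }
  if (is.null(best)) return(NULL)

  startS <- q$window_start_s[best[1L]]
  endS <- if (!is.null(fps))
    q$window_start_s[best[2L]] + q$n_frames[best[2L]] / fps
  else q$window_start_s[best[2L]] + window
  if ((endS - startS) < minSpan) return(NULL)
  list(start = startS, end = endS)
}
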