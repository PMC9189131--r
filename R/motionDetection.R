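#' Calibrate the frame-subtraction pixel threshold from an empty chamber
#'
#' Computes the absolute difference of every consecutive frame pair of a
#' worm-free chamber stack, pools all pixel values of all subtracted images,
#' and returns their mean plus five (population) standard deviations as the
#' pixel threshold for [classifyActivity()].
#'
#' @param emptyStack numeric array, height x width x frames (>= 2 frames),
#'   from a chamber that does not contain a worm.
#' @return a [CalibrationResult-class].
#'
#' @examples
#' stk <- array(rnorm(32 * 32 * 50, 100, 2), dim = c(32, 32, 50))
#' calibrateThreshold(stk)
#' @export
calibrateThreshold <- function(emptyStack) {
  stopIfNot(is.array(emptyStack) && length(dim(emptyStack)) == 3L,
            "emptyStack must be a height x width x frames array")
  n <- dim(emptyStack)[3L]
  stopIfNot(n >= 2L, "calibration requires at least 2 frames")
  d <- abs(emptyStack[, , 2:n, drop = FALSE] -
             emptyStack[, , 1:(n - 1L), drop = FALSE])
  m <- mean(d)
  s <- popSd(as.vector(d))
  new("CalibrationResult", pixelThreshold = m + 5 * s, mean = m, sd = s,
      nFramesUsed = as.integer(n))
}

#' Score per-frame locomotor activity by frame subtraction
#'
#' For each consecutive frame pair, counts the pixels whose absolute
#' difference strictly exceeds the calibrated pixel threshold; a frame is
#' judged locomotor active iff that count strictly exceeds
#' `pixelCountCutoff` (100 by default). N frames yield N-1 subtracted
#' images; the state of pair (i, i+1) is assigned to frame i+1 and the
#' first frame inherits the second frame's state, so the returned trace has
#' one entry per frame.
#'
#' @param stack numeric array, height x width x frames (>= 2 frames).
#' @param calib a [CalibrationResult-class] from [calibrateThreshold()].
#' @param fps frames per second of the recording.
#' @param pixelCountCutoff changed-pixel count above which a frame is
#'   active (strict exceedance).
#' @return an [ActivityTrace-class].
#' @seealso [segmentBouts()] for downstream bout segmentation.
#' @export
classifyActivity <- function(stack, calib, fps, pixelCountCutoff = 100) {
  stopIfNot(is.array(stack) && length(dim(stack)) == 3L,
            "stack must be a height x width x frames array")
  stopIfNot(is(calib, "CalibrationResult"),
            "calib must be a CalibrationResult")
  stopIfNot(fps > 0, "fps must be positive")
  n <- dim(stack)[3L]
  stopIfNot(n >= 2L, "classification requires at least 2 frames")

  thr <- pixelThreshold(calib)
  changed <- numeric(n)
  for (t in 2:n) {
    changed[t] <- sum(abs(stack[, , t] - stack[, , t - 1L]) > thr)
  }
  changed[1L] <- changed[2L]
  new("ActivityTrace", fps = fps, changedPixels = changed,
      active = changed > pixelCountCutoff)
}

#' Re-score quiescence by the 1%-of-body-size rule (artificial-dirt mode)
#'
#' In freely crawling (artificial-dirt chamber) recordings a frame is judged
#' quiescent iff its locomotor activity (changed-pixel count) is strictly
#' below 1% of the worm's body size in pixels; all other frames are active.
#'
#' @param activity an [ActivityTrace-class] with changed-pixel counts.
#' @param bodySize worm body size in pixels (positive); see
#'   [estimateBodySize()].
#' @param fraction quiescence cutoff as a fraction of body size (0.01 by
#'   the published rule).
#' @return a new [ActivityTrace-class] with `active` re-derived and
#'   `bodySize` recorded.
#' @export
quiescenceByBodySize <- function(activity, bodySize, fraction = 0.01) {
  stopIfNot(is(activity, "ActivityTrace"),
            "activity must be an ActivityTrace")
  stopIfNot(length(bodySize) == 1L && is.finite(bodySize) && bodySize > 0,
            "bodySize must be a single positive number")
  cp <- changedPixels(activity)
  quiescent <- cp < fraction * bodySize  # strict
  new("ActivityTrace", fps = fps(activity), changedPixels = cp,
      active = !quiescent, bodySize = bodySize)
}

#' Estimate worm body size from an image stack
#'
#' Thresholds the pooled pixel intensities with Otsu's method, counts
#' foreground pixels per frame, and returns the median count over frames as
#' the body size. If the foreground is not clearly separated from the
#' background (mean separation below `minSeparation` background SDs, as in
#' an empty-chamber stack), an estimation error is raised.
#'
#' @param stack numeric array, height x width x frames.
#' @param minSeparation required foreground/background mean separation, in
#'   units of the background SD.
#' @return body size in pixels (median foreground area over frames).
#' @export
estimateBodySize <- function(stack, minSeparation = 4) {
  stopIfNot(is.array(stack) && length(dim(stack)) == 3L,
            "stack must be a height x width x frames array")
  v <- as.vector(stack)
  thr <- otsuThreshold(v)
  fg <- v > thr
  if (!any(fg) || all(fg))
    stop("no foreground detected in stack", call. = FALSE)
  sdBg <- stats::sd(v[!fg])
  if (!is.finite(sdBg) || sdBg == 0) sdBg <- .Machine$double.eps
  if ((mean(v[fg]) - mean(v[!fg])) < minSeparation * sdBg)
    stop("no foreground detected: foreground/background separation too low",
         call. = FALSE)
  n <- dim(stack)[3L]
  counts <- vapply(seq_len(n), function(t) sum(stack[, , t] > thr),
                   numeric(1L))
  stats::median(counts)
}

## Otsu's threshold on a 256-bin histogram: maximizes between-class variance
otsuThreshold <- function(x, nBins = 256L) {
  rng <- range(x)
  if (rng[1L] == rng[2L]) return(rng[1L])
  breaks <- seq(rng[1L], rng[2L], length.out = nBins + 1L)
  h <- tabulate(findInterval(x, breaks, rightmost.closed = TRUE),
                nbins = nBins)
  p <- h / sum(h)
  omega <- cumsum(p)
  mids <- (breaks[-1L] + breaks[-(nBins + 1L)]) / 2
  mu <- cumsum(p * mids)
  muT <- mu[nBins]
  denom <- omega * (1 - omega)
  sigmaB <- ifelse(denom > 0, (muT * omega - mu)^2 / denom, 0)
  mids[which.max(sigmaB)]
}
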