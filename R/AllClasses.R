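#' @import methods
NULL

## Central containers. All intervals are half-open [start, end) in seconds,
## frames are 1-based in R vectors but frame i spans [(i-1)/fps, i/fps).

#' ActivityTrace: per-frame locomotor activity
#'
#' Holds the per-frame changed-pixel counts produced by frame subtraction,
#' the derived binary locomotor state (`TRUE` = locomotor active), the frame
#' rate, and optionally the worm body size in pixels (used by the
#' artificial-dirt 1%-of-body-size quiescence rule).
#'
#' @slot fps frames per second (positive scalar).
#' @slot changedPixels numeric vector, changed-pixel count per frame.
#' @slot active logical vector, per-frame locomotor state, same length.
#' @slot bodySize numeric scalar, worm area in pixels, or `NA` when unused.
#'
#' @seealso [classifyActivity()], [quiescenceByBodySize()], [segmentBouts()]
#' @export
setClass("ActivityTrace",
  representation(
    fps = "numeric",
    changedPixels = "numeric",
    active = "logical",
    bodySize = "numeric"
  ),
  prototype(bodySize = NA_real_)
)

setValidity("ActivityTrace", function(object) {
  msg <- character()
  if (length(object@fps) != 1L || !is.finite(object@fps) || object@fps <= 0)
    msg <- c(msg, "fps must be a single positive number")
  if (length(object@active) != length(object@changedPixels))
    msg <- c(msg, "active and changedPixels must have the same length")
  if (any(object@changedPixels < 0, na.rm = TRUE))
    msg <- c(msg, "changedPixels must be non-negative")
  if (length(msg)) msg else TRUE
})

#' BoutSeries: sleep/motion partition of a recording
#'
#' An ordered set of typed bouts tiling `[0, totalDuration)` exactly, with
#' strictly alternating kinds. Sleep bouts are maximal quiescent runs whose
#' duration strictly exceeds `minSleepDuration`; everything else is motion.
#'
#' @slot bouts data.frame with columns `kind` ("sleep"/"motion"), `start`,
#'   `end`, `duration` (seconds) and `atEdge` (touches recording start/end).
#' @slot fps frames per second of the underlying trace.
#' @slot totalDuration recording length in seconds.
#' @slot minSleepDuration minimum sleep-bout duration rule used (seconds).
#'
#' @seealso [segmentBouts()], [filterBouts()], [bouts()]
#' @export
setClass("BoutSeries",
  representation(
    bouts = "data.frame",
    fps = "numeric",
    totalDuration = "numeric",
    minSleepDuration = "numeric"
  )
)

setValidity("BoutSeries", function(object) {
  b <- object@bouts
  msg <- character()
  need <- c("kind", "start", "end", "duration", "atEdge")
  if (!all(need %in% names(b)))
    return(paste("bouts must have columns", paste(need, collapse = ", ")))
  if (nrow(b)) {
    if (!all(b$kind %in% c("sleep", "motion")))
      msg <- c(msg, "bout kind must be 'sleep' or 'motion'")
    if (any(b$end <= b$start))
      msg <- c(msg, "every bout must satisfy end > start")
    tol <- 1e-8
    if (abs(b$start[1L]) > tol ||
        abs(b$end[nrow(b)] - object@totalDuration) > tol)
      msg <- c(msg, "bouts must span [0, totalDuration)")
    if (nrow(b) > 1L) {
      if (any(abs(b$start[-1L] - b$end[-nrow(b)]) > tol))
        msg <- c(msg, "bouts must tile without gaps or overlaps")
      if (any(b$kind[-1L] == b$kind[-nrow(b)]))
        msg <- c(msg, "bout kinds must strictly alternate")
    }
  }
  if (length(msg)) msg else TRUE
})

#' RatioTrace: ratiometric dR/R0 calcium trace for one neuron
#'
#' The GCaMP/RFP ratio R per frame, the session mean R0, and the fractional
#' change (R - R0)/R0. By construction `mean(drOverR0)` is zero (over the
#' frames where R is defined), an identity the validity method enforces.
#'
#' @slot fps frames per second.
#' @slot R numeric vector, GCaMP/RFP ratio per frame (may contain `NA` for
#'   tracking dropouts).
#' @slot R0 session mean of R (over non-missing frames).
#' @slot drOverR0 numeric vector, (R - R0)/R0 per frame.
#' @slot neuronId character label.
#'
#' @seealso [computeRatioTrace()], [classifyMotionActive()]
#' @export
setClass("RatioTrace",
  representation(
    fps = "numeric",
    R = "numeric",
    R0 = "numeric",
    drOverR0 = "numeric",
    neuronId = "character"
  )
)

setValidity("RatioTrace", function(object) {
  msg <- character()
  if (length(object@R) != length(object@drOverR0))
    msg <- c(msg, "R and drOverR0 must have the same length")
  if (length(object@R0) != 1L || !is.finite(object@R0) || object@R0 <= 0)
    msg <- c(msg, "R0 must be a single positive number")
  m <- mean(object@drOverR0, na.rm = TRUE)
  if (is.finite(m) && abs(m) > 1e-8)
    msg <- c(msg, "mean(drOverR0) must be 0 to numerical precision")
  if (length(msg)) msg else TRUE
})

#' GroundTruthSchedule: simulated bout schedule with generative truth
#'
#' Output of [simulateBoutSchedule()]: the continuous-time bout list, the
#' per-frame binary locomotor state derived from it, and the generative
#' parameters (homeostatic gain etc.) for recovery tests.
#'
#' @slot bouts data.frame (`kind`, `start`, `end`, `duration`) tiling
#'   `[0, totalDuration)` with strictly alternating kinds.
#' @slot state logical vector, per-frame ground-truth locomotor state
#'   (`TRUE` = motion).
#' @slot fps frames per second of the state vector.
#' @slot totalDuration recording length (seconds).
#' @slot params list of true generative parameters.
#' @export
setClass("GroundTruthSchedule",
  representation(
    bouts = "data.frame",
    state = "logical",
    fps = "numeric",
    totalDuration = "numeric",
    params = "list"
  )
)

setValidity("GroundTruthSchedule", function(object) {
  b <- object@bouts
  msg <- character()
  tol <- 1e-8
  if (nrow(b)) {
    if (abs(b$start[1L]) > tol ||
        abs(b$end[nrow(b)] - object@totalDuration) > tol)
      msg <- c(msg, "bouts must span [0, totalDuration)")
    if (nrow(b) > 1L && any(b$kind[-1L] == b$kind[-nrow(b)]))
      msg <- c(msg, "bout kinds must strictly alternate")
  }
  nExpect <- as.integer(round(object@totalDuration * object@fps))
  if (length(object@state) != nExpect)
    msg <- c(msg, "state length must equal round(totalDuration * fps)")
  if (length(msg)) msg else TRUE
})

#' CalibrationResult: empty-chamber subtraction threshold
#'
#' Pixel-level threshold for frame subtraction, defined as the mean plus five
#' (population) standard deviations of all pixel values pooled across all
#' subtracted images of a worm-free chamber recording.
#'
#' @slot pixelThreshold mean + 5 * sd, intensity units.
#' @slot mean pooled mean of subtracted pixel values.
#' @slot sd pooled population standard deviation.
#' @slot nFramesUsed number of frames in the calibration stack.
#' @seealso [calibrateThreshold()], [classifyActivity()]
#' @export
setClass("CalibrationResult",
  representation(
    pixelThreshold = "numeric",
    mean = "numeric",
    sd = "numeric",
    nFramesUsed = "integer"
  )
)

setValidity("CalibrationResult", function(object) {
  msg <- character()
  if (object@sd < 0) msg <- c(msg, "sd must be non-negative")
  if (abs(object@pixelThreshold - (object@mean + 5 * object@sd)) >
      1e-9 * max(1, abs(object@pixelThreshold)))
    msg <- c(msg, "pixelThreshold must equal mean + 5 * sd")
  if (length(msg)) msg else TRUE
})

#' StimExperiment: simulated optogenetic stimulation experiment
#'
#' Per-trial outcomes of a stimulation-at-motion-onset protocol: group labels
#' (treated/control), latency from stimulation to the first qualifying sleep
#' bout, censoring flags, and the per-trial locomotion traces aligned at the
#' stimulation onset.
#'
#' @slot trials data.frame with columns `trial`, `group`, `latency`
#'   (seconds, `NA` when censored), `censored` (logical).
#' @slot locomotion numeric matrix, frames x trials, locomotor activity.
#' @slot active logical matrix, frames x trials, binary locomotor state.
#' @slot fps frames per second.
#' @slot stimIndex 1-based frame index at which stimulation starts (time 0).
#' @slot stimDuration stimulation duration in seconds.
#' @export
setClass("StimExperiment",
  representation(
    trials = "data.frame",
    locomotion = "matrix",
    active = "matrix",
    fps = "numeric",
    stimIndex = "integer",
    stimDuration = "numeric"
  )
)

setValidity("StimExperiment", function(object) {
  msg <- character()
  if (ncol(object@locomotion) != nrow(object@trials))
    msg <- c(msg, "locomotion must have one column per trial")
  if (!identical(dim(object@locomotion), dim(object@active)))
    msg <- c(msg, "locomotion and active must have identical dimensions")
  if (object@stimIndex < 1L || object@stimIndex > nrow(object@locomotion))
    msg <- c(msg, "stimIndex must index a frame of the traces")
  if (length(msg)) msg else TRUE
})
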