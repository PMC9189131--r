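#' @rdname accessors
setMethod("fps", "ActivityTrace", function(object) object@fps)
#' @rdname accessors
setMethod("fps", "BoutSeries", function(object) object@fps)
#' @rdname accessors
setMethod("fps", "RatioTrace", function(object) object@fps)
#' @rdname accessors
setMethod("fps", "GroundTruthSchedule", function(object) object@fps)
#' @rdname accessors
setMethod("fps", "StimExperiment", function(object) object@fps)

#' @rdname accessors
setMethod("bouts", "BoutSeries", function(object) object@bouts)
#' @rdname accessors
setMethod("bouts", "GroundTruthSchedule", function(object) object@bouts)

#' @rdname accessors
setMethod("activeState", "ActivityTrace", function(object) object@active)
#' @rdname accessors
setMethod("changedPixels", "ActivityTrace", function(object)
  object@changedPixels)

#' @rdname accessors
setMethod("drOverR0", "RatioTrace", function(object) object@drOverR0)
#' @rdname accessors
setMethod("ratioR", "RatioTrace", function(object) object@R)
#' @rdname accessors
setMethod("ratioR0", "RatioTrace", function(object) object@R0)

#' @rdname accessors
setMethod("pixelThreshold", "CalibrationResult", function(object)
  object@pixelThreshold)

#' @rdname accessors
setMethod("totalDuration", "BoutSeries", function(object)
  object@totalDuration)
#' @rdname accessors
setMethod("totalDuration", "GroundTruthSchedule", function(object)
  object@totalDuration)

#' @rdname accessors
setMethod("trueState", "GroundTruthSchedule", function(object) object@state)

#' @rdname accessors
setMethod("trials", "StimExperiment", function(object) object@trials)
#' @rdname accessors
setMethod("locomotionTraces", "StimExperiment", function(object)
  object@locomotion)

setMethod("length", "ActivityTrace", function(x) length(x@active))
setMethod("length", "RatioTrace", function(x) length(x@R))

#' @describeIn stateVector frame states from the segmented bout table.
setMethod("stateVector", "BoutSeries", function(object) {
  framesFromBouts(object@bouts, object@fps, object@totalDuration)
})

#' @describeIn stateVector the stored ground-truth frame states.
setMethod("stateVector", "GroundTruthSchedule", function(object) object@state)

## shared helper: frame i (1-based) takes the kind of the bout containing
## its start time (i-1)/fps
framesFromBouts <- function(b, fps, totalDuration) {
  n <- as.integer(round(totalDuration * fps))
  state <- logical(n)
  for (k in seq_len(nrow(b))) {
    i0 <- as.integer(round(b$start[k] * fps)) + 1L
    i1 <- as.integer(round(b$end[k] * fps))
    i1 <- min(i1, n)
    if (i1 >= i0) state[i0:i1] <- (b$kind[k] == "motion")
  }
  state
}

setMethod("show", "ActivityTrace", function(object) {
  cat("ActivityTrace:", length(object@active), "frames at",
      object@fps, "fps\n")
  cat("  active frames:", sum(object@active), sprintf(
    "(%.1f%%)\n", 100 * mean(object@active)))
  if (!is.na(object@bodySize))
    cat("  body size:", object@bodySize, "pixels\n")
})

setMethod("show", "BoutSeries", function(object) {
  b <- object@bouts
  cat("BoutSeries:", nrow(b), "bouts over", object@totalDuration,
      "s at", object@fps, "fps\n")
  cat("  sleep bouts:", sum(b$kind == "sleep"),
      " motion bouts:", sum(b$kind == "motion"), "\n")
  cat("  min sleep-bout duration:", object@minSleepDuration, "s\n")
})

setMethod("show", "RatioTrace", function(object) {
  cat("RatioTrace for", object@neuronId, ":", length(object@R),
      "frames at", object@fps, "fps\n")
  cat(sprintf("  R0 = %.4f, dR/R0 range [%.3f, %.3f]\n", object@R0,
      min(object@drOverR0, na.rm = TRUE),
      max(object@drOverR0, na.rm = TRUE)))
})

setMethod("show", "GroundTruthSchedule", function(object) {
  cat("GroundTruthSchedule:", nrow(object@bouts), "bouts,",
      object@totalDuration, "s at", object@fps, "fps\n")
  p <- object@params
  if (length(p))
    cat("  true params:", paste(names(p), unlist(p), sep = "=",
        collapse = ", "), "\n")
})

setMethod("show", "CalibrationResult", function(object) {
  cat(sprintf(
    "CalibrationResult: threshold %.4f (mean %.4f + 5 x sd %.4f, %d frames)\n",
    object@pixelThreshold, object@mean, object@sd, object@nFramesUsed))
})

setMethod("show", "StimExperiment", function(object) {
  tab <- table(object@trials$group)
  cat("StimExperiment:", nrow(object@trials), "trials (",
      paste(names(tab), tab, sep = "=", collapse = ", "), ") at",
      object@fps, "fps\n")
  cat("  censored:", sum(object@trials$censored), "\n")
})
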