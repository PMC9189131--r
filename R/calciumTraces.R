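#' Compute a ratiometric dR/R0 trace from dual-channel fluorescence
#'
#' Calcium activity is estimated as the fractional change of the GCaMP/RFP
#' ratio, `(R - R0)/R0`, where `R = gcamp/rfp` per frame and `R0` is the
#' mean of R over the whole session. Frames where either channel is missing
#' (tracking dropouts) are excluded from `R0` and carried as `NA`; their
#' count is reported via a message. Frames with non-positive RFP are a data
#' error (the ratio is undefined there) and are reported by frame number.
#'
#' @param gcamp numeric vector, GCaMP fluorescence per frame.
#' @param rfp numeric vector, RFP fluorescence per frame, same length.
#' @param fps frames per second.
#' @param neuronId label for the neuron (default "neuron").
#' @return a [RatioTrace-class].
#'
#' @examples
#' tr <- computeRatioTrace(gcamp = c(100, 200, 300), rfp = c(100, 100, 100),
#'                         fps = 10)
#' drOverR0(tr)
#' @export
computeRatioTrace <- function(gcamp, rfp, fps, neuronId = "neuron") {
  stopIfNot(length(gcamp) == length(rfp),
            "gcamp and rfp must have the same length")
  stopIfNot(length(gcamp) >= 2L, "traces must contain at least 2 frames")
  stopIfNot(fps > 0, "fps must be positive")

  bad <- which(!is.na(rfp) & rfp <= 0)
  if (length(bad))
    stop("rfp must be strictly positive; offending frames: ",
         paste(utils::head(bad, 10L), collapse = ", "),
         if (length(bad) > 10L) " ..." else "", call. = FALSE)

  R <- gcamp / rfp
  nDropped <- sum(is.na(R))
  if (nDropped > 0)
    message(nDropped, " frame(s) with missing fluorescence excluded from R0")
  R0 <- mean(R, na.rm = TRUE)
  stopIfNot(is.finite(R0) && R0 > 0,
            "session mean ratio R0 must be positive")
  new("RatioTrace", fps = fps, R = R, R0 = R0,
      drOverR0 = (R - R0) / R0, neuronId = neuronId)
}

#' Classify a neuron as motion-active by the 20% enrichment rule
#'
#' A neuron is motion-active when its average dR/R0 over motion-bout frames
#' exceeds the session average by the margin. Because the session mean of
#' dR/R0 is identically zero by construction, the criterion reduces to
#' motion-bout mean dR/R0 > `margin` (0.20 absolute dR/R0 units by
#' default); the comparison is strict. Missing frames are excluded from
#' both means.
#'
#' @param trace a [RatioTrace-class].
#' @param series a [BoutSeries-class] covering the same recording.
#' @param margin required enrichment in absolute dR/R0 units.
#' @return list with `motionActive` (logical), `motionMean`, `sessionMean`
#'   and `margin`.
#' @export
classifyMotionActive <- function(trace, series, margin = 0.20) {
  stopIfNot(is(trace, "RatioTrace"), "trace must be a RatioTrace")
  stopIfNot(is(series, "BoutSeries"), "series must be a BoutSeries")
  state <- stateVector(series)
  stopIfNot(length(state) == length(trace@drOverR0),
            "trace and bout series must cover the same recording")
  if (!any(state))
    stop("no motion bouts in series; classification undefined",
         call. = FALSE)
  dr <- drOverR0(trace)
  motionMean <- mean(dr[state], na.rm = TRUE)
  sessionMean <- mean(dr, na.rm = TRUE)
  list(
    motionActive = motionMean > sessionMean + margin,
    motionMean = motionMean,
    sessionMean = sessionMean,
    margin = margin
  )
}
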