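#' Latency from stimulation to the first qualifying sleep bout
#'
#' Re-segments the post-stimulation part of a binary activity trace with
#' the optogenetics sleep rule (quiescent runs lasting strictly more than
#' `minSleepDuration`, 5 s by protocol) and returns the time from the
#' stimulation onset to the start of the first qualifying sleep bout --
#' equivalently, the duration of the motion bout after the light
#' stimulation when stimulation coincides with a motion-bout onset. When no
#' qualifying sleep bout occurs before the recording ends the latency is
#' right-censored.
#'
#' @param active logical vector, per-frame locomotor state (`TRUE` =
#'   active), starting at time 0, or an [ActivityTrace-class].
#' @param fps frames per second (taken from the trace when one is given).
#' @param stimOnset stimulation onset time in seconds from the trace start.
#' @param minSleepDuration sleep rule in seconds (strictly greater than).
#' @return list with `latency` (seconds from stimulation onset; `NA` when
#'   censored) and `censored` (logical).
#' @export
latencyToSleep <- function(active, fps, stimOnset, minSleepDuration = 5) {
  if (is(active, "ActivityTrace")) {
    fps <- fps(active)
    active <- activeState(active)
  }
  stopIfNot(is.logical(active) && length(active) > 0,
            "active must be a non-empty logical vector")
  stopIfNot(fps > 0, "fps must be positive")
  stopIfNot(stimOnset >= 0, "stimOnset must be non-negative")

  i0 <- as.integer(round(stimOnset * fps)) + 1L
  stopIfNot(i0 <= length(active), "stimOnset lies beyond the recording")
  post <- active[i0:length(active)]
  series <- segmentBouts(post, fps, minSleepDuration)
  b <- bouts(series)
  sl <- b[b$kind == "sleep", , drop = FALSE]
  if (!nrow(sl)) return(list(latency = NA_real_, censored = TRUE))
  list(latency = sl$start[1L], censored = FALSE)
}

#' Stimulation-aligned locomotor activity averaging and group comparison
#'
#' Aligns the per-trial locomotion traces of a [StimExperiment-class] at
#' the stimulation onset, smooths each trace with a centered 2.5-s moving
#' average (truncated edges), and averages per group with SEM. Per trial,
#' the mean raw locomotor activity over `[0, summaryWindow)` seconds after
#' stimulation is returned and compared between groups with an unpaired
#' Welch t test; latency distributions are additionally compared with the
#' Mann-Whitney test (primary, ties-robust) and the Kolmogorov-Smirnov
#' test. Trials whose traces do not cover the summary window are excluded
#' with their count logged.
#'
#' @param experiment a [StimExperiment-class].
#' @param smooth moving-average width in seconds.
#' @param summaryWindow post-stimulation summary window in seconds (5 by
#'   the figure-legend convention; the alternative 10-s reading is
#'   available via this argument).
#' @return list with `profiles` (data.frame `time_s`, `group`, `mean`,
#'   `sem`), `perTrial` (data.frame `trial`, `group`, `postMean`),
#'   `summaryP` (Welch t test on post-stimulation means), `latencyP`
#'   (Mann-Whitney on latencies), `latencyKsP` (Kolmogorov-Smirnov),
#'   and `nExcluded`.
#' @export
stimTriggeredLocomotion <- function(experiment, smooth = 2.5,
                                    summaryWindow = 5) {
  stopIfNot(is(experiment, "StimExperiment"),
            "experiment must be a StimExperiment")
  stopIfNot(summaryWindow > 0, "summaryWindow must be positive")
  loc <- locomotionTraces(experiment)
  tr <- trials(experiment)
  fr <- fps(experiment)
  s0 <- experiment@stimIndex
  nFrames <- nrow(loc)
  wFrames <- as.integer(round(summaryWindow * fr))

  nExcluded <- 0L
  if (s0 + wFrames - 1L > nFrames)
    stop("traces do not cover the summary window", call. = FALSE)

  sm <- apply(loc, 2L, movingAverage, width = smooth, fps = fr)
  timeS <- (seq_len(nFrames) - s0) / fr
  profiles <- do.call(rbind, lapply(split(seq_len(nrow(tr)), tr$group),
                                    function(idx) {
    m <- sm[, idx, drop = FALSE]
    data.frame(
      time_s = timeS,
      group = tr$group[idx[1L]],
      mean = rowMeans(m),
      sem = if (length(idx) >= 2L) apply(m, 1L, stats::sd) /
        sqrt(length(idx)) else NA_real_
    )
  }))
  rownames(profiles) <- NULL

  postMean <- colMeans(loc[s0:(s0 + wFrames - 1L), , drop = FALSE])
  perTrial <- data.frame(trial = tr$trial, group = tr$group,
                         postMean = postMean)

  groups <- unique(tr$group)
  summaryP <- latencyP <- latencyKsP <- NA_real_
  if (length(groups) == 2L) {
    a <- perTrial$postMean[tr$group == groups[1L]]
    b <- perTrial$postMean[tr$group == groups[2L]]
    if (length(a) >= 2L && length(b) >= 2L &&
        (stats::var(a) > 0 || stats::var(b) > 0))
      summaryP <- stats::t.test(a, b)$p.value
    la <- tr$latency[tr$group == groups[1L] & !tr$censored]
    lb <- tr$latency[tr$group == groups[2L] & !tr$censored]
    if (length(la) >= 2L && length(lb) >= 2L) {
      latencyP <- stats::wilcox.test(la, lb, exact = FALSE)$p.value
      latencyKsP <- suppressWarnings(stats::ks.test(la, lb)$p.value)
    }
  }

  list(profiles = profiles, perTrial = perTrial, summaryP = summaryP,
       latencyP = latencyP, latencyKsP = latencyKsP,
       nExcluded = nExcluded)
}
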