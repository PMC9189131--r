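#' Simulate an alternating motion/sleep bout schedule with homeostatic
#' coupling
#'
#' Generates a lethargus-like bout schedule: the recording alternates
#' strictly between motion and sleep bouts, starting with a motion bout.
#' Motion-bout durations are drawn from a log-normal distribution with
#' arithmetic mean `motionMean` (positive and right-skewed, matching the
#' shape of observed bout-duration histograms). Each sleep bout's duration
#' is homeostatically coupled to the immediately preceding motion bout:
#'
#' \deqn{S = \max(\mathrm{minBout},\ \mathrm{sleepBase} + b\,M + \epsilon),
#'   \quad \epsilon \sim N(0, \mathrm{sleepNoiseSd}^2)}
#'
#' where `M` is the prior motion-bout duration and `b = homeostaticGain`.
#' The last bout is truncated at `totalDuration`. A per-frame binary state
#' vector is derived at `fps` (frame i takes the state of the bout
#' containing its start time).
#'
#' @param totalDuration recording length in seconds.
#' @param fps frames per second of the derived state vector.
#' @param motionMean arithmetic mean of motion-bout durations (s).
#' @param motionSdlog log-scale SD of the motion-bout log-normal.
#' @param sleepBase baseline sleep-bout duration (s).
#' @param homeostaticGain coupling `b` between prior motion duration and
#'   sleep duration (dimensionless).
#' @param sleepNoiseSd SD of the Gaussian noise on sleep durations (s).
#' @param minBout floor on sleep-bout durations (s); the default keeps every
#'   simulated sleep bout detectable under the 6-s sleep rule.
#' @param seed integer RNG seed (required for reproducibility; default 1).
#' @return a [GroundTruthSchedule-class] carrying the bout table, the
#'   per-frame state, and the true generative parameters.
#'
#' @examples
#' sch <- simulateBoutSchedule(totalDuration = 600, fps = 10, seed = 7)
#' head(bouts(sch))
#' @export
simulateBoutSchedule <- function(totalDuration = 1200, fps = 10,
                                 motionMean = 30, motionSdlog = 0.6,
                                 sleepBase = 10, homeostaticGain = 0.5,
                                 sleepNoiseSd = 2, minBout = 7,
                                 seed = 1) {
  stopIfNot(totalDuration > 0, "totalDuration must be positive")
  stopIfNot(fps > 0, "fps must be positive")
  stopIfNot(motionMean > 0, "motionMean must be positive")
  stopIfNot(motionSdlog >= 0, "motionSdlog must be non-negative")
  stopIfNot(sleepBase >= 0, "sleepBase must be non-negative")
  stopIfNot(sleepNoiseSd >= 0, "sleepNoiseSd must be non-negative")
  stopIfNot(minBout >= 0, "minBout must be non-negative")

  meanlog <- log(motionMean) - motionSdlog^2 / 2

  sim <- withSeed(seed, {
    kind <- character()
    dur <- numeric()
    t <- 0
    motion <- TRUE
    lastMotion <- NA_real_
    while (t < totalDuration) {
      if (motion) {
        d <- stats::rlnorm(1L, meanlog = meanlog, sdlog = motionSdlog)
        lastMotion <- d
      } else {
        d <- sleepBase + homeostaticGain * lastMotion +
          stats::rnorm(1L, 0, sleepNoiseSd)
        d <- max(minBout, d)
      }
      kind <- c(kind, if (motion) "motion" else "sleep")
      dur <- c(dur, d)
      t <- t + d
      motion <- !motion
    }
    list(kind = kind, dur = dur)
  })

  end <- cumsum(sim$dur)
  start <- c(0, end[-length(end)])
  end[length(end)] <- totalDuration  # truncate the last bout
  b <- data.frame(
    kind = sim$kind, start = start, end = end,
    duration = end - start, stringsAsFactors = FALSE
  )

  n <- as.integer(round(totalDuration * fps))
  frameStart <- (seq_len(n) - 1L) / fps
  idx <- findInterval(frameStart, b$start)
  state <- b$kind[idx] == "motion"

  new("GroundTruthSchedule",
    bouts = b, state = state, fps = fps, totalDuration = totalDuration,
    params = list(
      motionMean = motionMean, motionSdlog = motionSdlog,
      sleepBase = sleepBase, homeostaticGain = homeostaticGain,
      sleepNoiseSd = sleepNoiseSd, minBout = minBout, seed = seed
    ))
}
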