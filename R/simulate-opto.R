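#' Simulate an optogenetic stimulation-at-motion-onset experiment
#'
#' Each trial starts at a motion-bout onset with stimulation at time 0
#' (3 s of light by protocol). The motion-to-sleep (MS) transition is
#' sampled frame by frame from a per-second hazard `baselineHazard`; for
#' treated trials the hazard is multiplied by `stimHazardMultiplier` during
#' the effect window `[0, stimEffectWindow)`. The per-frame transition
#' probability is `1 - (1 - h)^(m / fps)` where `m` is the applicable
#' multiplier, so a hazard of 1 transitions at the first frame with
#' certainty. Control trials use the multiplier 1 throughout.
#'
#' Each trial also carries a locomotion trace aligned at the stimulation
#' onset: quiescent before time 0 (end of the preceding sleep bout), active
#' from 0 until the MS transition, then a sleep bout of `sleepDuration`
#' seconds, then active again until the trial ends. Locomotor activity is
#' drawn around `activeLevel` during motion frames and near zero during
#' quiescent frames.
#'
#' @param nTrials trials per group.
#' @param baselineHazard per-second MS transition probability in (0, 1].
#' @param stimHazardMultiplier hazard multiplier (>= 1) applied to treated
#'   trials during the effect window.
#' @param stimEffectWindow effect window after stimulation onset (s).
#' @param stimDuration stimulation duration (s); 3 by protocol.
#' @param fps frames per second (2 by protocol).
#' @param trialDuration recorded time after stimulation (s).
#' @param preDuration recorded time before stimulation (s).
#' @param sleepDuration duration of the sleep bout entered at the MS
#'   transition (s).
#' @param activeLevel mean locomotor activity during motion frames
#'   (changed-pixel-like units).
#' @param seed integer RNG seed (default 1).
#' @return a [StimExperiment-class].
#'
#' @examples
#' ex <- simulateOptogenetics(nTrials = 20, seed = 5)
#' head(trials(ex))
#' @export
simulateOptogenetics <- function(nTrials = 100, baselineHazard = 0.1,
                                 stimHazardMultiplier = 4,
                                 stimEffectWindow = 10, stimDuration = 3,
                                 fps = 2, trialDuration = 60,
                                 preDuration = 10, sleepDuration = 15,
                                 activeLevel = 150, seed = 1) {
  stopIfNot(nTrials >= 1, "nTrials must be at least 1")
  stopIfNot(baselineHazard > 0 && baselineHazard <= 1,
            "baselineHazard must be in (0, 1]")
  stopIfNot(stimHazardMultiplier >= 1, "stimHazardMultiplier must be >= 1")
  stopIfNot(stimEffectWindow >= 0, "stimEffectWindow must be non-negative")
  stopIfNot(stimDuration > 0, "stimDuration must be positive")
  stopIfNot(fps > 0 && trialDuration > 0 && preDuration >= 0,
            "fps and durations must be positive")

  nPre <- as.integer(round(preDuration * fps))
  nPost <- as.integer(round(trialDuration * fps))
  nFrames <- nPre + nPost
  stimIndex <- nPre + 1L
  nWin <- as.integer(round(stimEffectWindow * fps))

  groups <- rep(c("treated", "control"), each = nTrials)
  nTot <- length(groups)

  withSeed(seed, {
    latency <- rep(NA_real_, nTot)
    censored <- logical(nTot)
    active <- matrix(FALSE, nFrames, nTot)
    locomotion <- matrix(0, nFrames, nTot)

    for (i in seq_len(nTot)) {
      mult <- rep(1, nPost)
      if (groups[i] == "treated" && nWin > 0)
        mult[seq_len(min(nWin, nPost))] <- stimHazardMultiplier
      p <- 1 - (1 - baselineHazard)^(mult / fps)
      hit <- which(stats::runif(nPost) < p)
      if (length(hit)) {
        f <- hit[1L]
        latency[i] <- f / fps
      } else {
        f <- NA_integer_
        censored[i] <- TRUE
      }

      st <- logical(nFrames)  # TRUE = motion
      if (is.na(f)) {
        st[stimIndex:nFrames] <- TRUE
      } else {
        moveEnd <- stimIndex + f - 1L
        st[stimIndex:moveEnd] <- TRUE
        sleepEnd <- min(nFrames, moveEnd + as.integer(round(
          sleepDuration * fps)))
        if (sleepEnd < nFrames) st[(sleepEnd + 1L):nFrames] <- TRUE
      }
      active[, i] <- st
      loc <- abs(stats::rnorm(nFrames, 3, 2))
      loc[st] <- pmax(0, stats::rnorm(sum(st), activeLevel,
                                      activeLevel / 8))
      locomotion[, i] <- loc
    }

    new("StimExperiment",
      trials = data.frame(
        trial = seq_len(nTot), group = groups,
        latency = latency, censored = censored,
        stringsAsFactors = FALSE
      ),
      locomotion = locomotion, active = active, fps = fps,
      stimIndex = stimIndex, stimDuration = stimDuration)
  })
}
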