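#' Simulate a dual-channel calcium recording from a bout schedule
#'
#' Generates a latent calcium-like signal `C(t)` that ramps linearly during
#' motion bouts and decays exponentially during sleep bouts, observed through
#' two noisy fluorescence channels:
#'
#' \deqn{dC/dt = k \textrm{ (motion)}, \qquad dC/dt = -C/\tau
#'   \textrm{ (sleep)}, \qquad C(0) = 0}
#'
#' \deqn{\mathrm{GCaMP}(t) = \mathrm{baseline} + \mathrm{gain}\,C(t) +
#'   \epsilon_1, \qquad \mathrm{RFP}(t) = \mathrm{level} + \epsilon_2}
#'
#' Integration uses exact per-frame updates on the frame grid: during motion
#' frames `C` increases by `rampRate / fps`, during sleep frames `C` is
#' multiplied by `exp(-1 / (fps * decayTau))`, so the noise-free signal
#' matches the analytic linear-ramp and exponential-decay solutions exactly.
#' With zero noise, the latent peak within each motion bout falls on its
#' final frame.
#'
#' @param schedule a [GroundTruthSchedule-class].
#' @param rampRate latent rise rate `k` during motion, signal units per
#'   second.
#' @param decayTau exponential decay time constant during sleep (s).
#' @param gcampGain fluorescence units per unit latent signal.
#' @param gcampBaseline GCaMP baseline fluorescence (positive).
#' @param rfpLevel RFP fluorescence level (positive).
#' @param channelNoiseSd Gaussian noise SD added independently to each
#'   channel, fluorescence units.
#' @param seed integer RNG seed (default 1).
#' @return data.frame with columns `frame`, `time_s`, `gcamp`, `rfp` and
#'   `latent` (the noise-free latent signal, kept as ground truth).
#'
#' @examples
#' sch <- simulateBoutSchedule(totalDuration = 300, seed = 2)
#' tr <- simulateCalcium(sch, seed = 2)
#' head(tr)
#' @export
simulateCalcium <- function(schedule, rampRate = 0.08, decayTau = 3,
                            gcampGain = 100, gcampBaseline = 100,
                            rfpLevel = 200, channelNoiseSd = 2,
                            seed = 1) {
  stopIfNot(is(schedule, "GroundTruthSchedule"),
            "schedule must be a GroundTruthSchedule")
  stopIfNot(rampRate >= 0, "rampRate must be non-negative")
  stopIfNot(decayTau > 0, "decayTau must be positive")
  stopIfNot(gcampBaseline > 0, "gcampBaseline must be positive")
  stopIfNot(rfpLevel > 0, "rfpLevel must be positive")
  stopIfNot(channelNoiseSd >= 0, "channelNoiseSd must be non-negative")

  state <- trueState(schedule)
  n <- length(state)
  stopIfNot(n >= 2L, "schedule must contain at least 2 frames")
  dt <- 1 / fps(schedule)

  C <- numeric(n)
  r <- rle(state)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  c0 <- 0
  decay <- exp(-dt / decayTau)
  for (k in seq_along(r$lengths)) {
    len <- r$lengths[k]
    seg <- seq_len(len)
    if (r$values[k]) {
      C[starts[k]:ends[k]] <- c0 + rampRate * dt * seg
    } else {
      C[starts[k]:ends[k]] <- c0 * decay^seg
    }
    c0 <- C[ends[k]]
  }

  noise <- withSeed(seed, {
    list(g = stats::rnorm(n, 0, channelNoiseSd),
         r = stats::rnorm(n, 0, channelNoiseSd))
  })

  data.frame(
    frame = seq_len(n),
    time_s = (seq_len(n) - 1L) * dt,
    gcamp = gcampBaseline + gcampGain * C + noise$g,
    rfp = rfpLevel + noise$r,
    latent = C
  )
}
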