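#' Render a synthetic behaviour video from a bout schedule
#'
#' Produces a grayscale image stack containing a bright worm blob on a dark
#' background. During motion frames the blob translates by `jitterPx` pixels
#' (in a random cardinal direction); during sleep frames it is static, so
#' consecutive frames differ by pixel noise only. A matched empty-chamber
#' stack (background plus noise, no worm) of `emptyFrames` frames is
#' returned for threshold calibration.
#'
#' The blob is the `wormArea` pixels nearest the (integer) blob centre, so
#' its area is exactly `wormArea`. If a step would push the blob over a
#' border, the centre position is reflected back inside (never an error).
#'
#' @param schedule a [GroundTruthSchedule-class]; one video frame is
#'   rendered per schedule frame.
#' @param frameShape integer vector of length 2, frame height and width in
#'   pixels.
#' @param wormArea blob size in pixels (must be smaller than the frame).
#' @param jitterPx displacement per motion frame, pixels.
#' @param pixelNoiseSd Gaussian pixel noise SD, intensity units (0-255
#'   scale).
#' @param background background intensity.
#' @param wormIntensity blob intensity.
#' @param emptyFrames number of frames in the empty-chamber stack.
#' @param seed integer RNG seed (default 1).
#' @return list with elements `stack` (height x width x frames array),
#'   `empty` (same shape, `emptyFrames` frames), and `positions`
#'   (frames x 2 matrix of blob centres, ground truth).
#'
#' @examples
#' sch <- simulateBoutSchedule(totalDuration = 30, fps = 10, seed = 3)
#' vid <- renderVideo(sch, emptyFrames = 50, seed = 3)
#' dim(vid$stack)
#' @export
renderVideo <- function(schedule, frameShape = c(64, 64), wormArea = 600,
                        jitterPx = 3, pixelNoiseSd = 2, background = 30,
                        wormIntensity = 200, emptyFrames = 500, seed = 1) {
  stopIfNot(is(schedule, "GroundTruthSchedule"),
            "schedule must be a GroundTruthSchedule")
  stopIfNot(length(frameShape) == 2L && all(frameShape >= 4),
            "frameShape must be two pixel dimensions")
  stopIfNot(wormArea >= 1 && wormArea < prod(frameShape),
            "wormArea must be positive and smaller than the frame")
  stopIfNot(jitterPx >= 0, "jitterPx must be non-negative")
  stopIfNot(pixelNoiseSd >= 0, "pixelNoiseSd must be non-negative")
  stopIfNot(emptyFrames >= 2, "emptyFrames must be at least 2")

  state <- trueState(schedule)
  n <- length(state)
  stopIfNot(n >= 2L, "schedule must contain at least 2 frames")
  h <- as.integer(frameShape[1L]); w <- as.integer(frameShape[2L])

  ## blob mask offsets: the wormArea pixels nearest the centre, with
  ## deterministic tie-breaking so the blob shape is identical every frame
  rmax <- ceiling(sqrt(wormArea / pi)) + 2L
  off <- expand.grid(dy = -rmax:rmax, dx = -rmax:rmax)
  d2 <- off$dy^2 + off$dx^2
  ord <- order(d2, off$dy, off$dx)
  off <- off[ord[seq_len(wormArea)], ]
  reach <- max(abs(c(off$dy, off$dx)))
  stopIfNot(2 * reach + 2 < min(h, w),
            "wormArea too large for the frame shape")

  lo <- reach + 1L
  hiY <- h - reach; hiX <- w - reach
  reflect <- function(p, lo, hi) {
    # reflect into [lo, hi]
    span <- hi - lo
    if (span <= 0) return(lo)
    q <- (p - lo) %% (2 * span)
    if (q > span) q <- 2 * span - q
    lo + q
  }

  withSeed(seed, {
    pos <- matrix(0L, n, 2L)
    cy <- as.integer(round((lo + hiY) / 2))
    cx <- as.integer(round((lo + hiX) / 2))
    dirs <- matrix(c(1L, 0L, -1L, 0L, 0L, 1L, 0L, -1L), ncol = 2L,
                   byrow = TRUE)
    step <- as.integer(round(jitterPx))
    stack <- array(0, dim = c(h, w, n))
    for (t in seq_len(n)) {
      if (t > 1L && state[t] && step > 0L) {
        ## prefer directions whose full step stays inside the frame, so
        ## the displacement magnitude is exactly `step`; reflect only when
        ## the frame is too small for any full step
        candY <- cy + dirs[, 1L] * step
        candX <- cx + dirs[, 2L] * step
        ok <- candY >= lo & candY <= hiY & candX >= lo & candX <= hiX
        if (any(ok)) {
          pick <- which(ok)[sample.int(sum(ok), 1L)]
          cy <- candY[pick]
          cx <- candX[pick]
        } else {
          d <- dirs[sample.int(4L, 1L), ]
          cy <- as.integer(reflect(cy + d[1L] * step, lo, hiY))
          cx <- as.integer(reflect(cx + d[2L] * step, lo, hiX))
        }
      }
      pos[t, ] <- c(cy, cx)
      fr <- matrix(background, h, w)
      fr[cbind(cy + off$dy, cx + off$dx)] <- wormIntensity
      if (pixelNoiseSd > 0)
        fr <- fr + matrix(stats::rnorm(h * w, 0, pixelNoiseSd), h, w)
      stack[, , t] <- fr
    }
    empty <- array(background, dim = c(h, w, emptyFrames))
    if (pixelNoiseSd > 0)
      empty <- empty + array(stats::rnorm(h * w * emptyFrames, 0,
                                          pixelNoiseSd),
                             dim = c(h, w, emptyFrames))
    list(stack = stack, empty = empty, positions = pos)
  })
}
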