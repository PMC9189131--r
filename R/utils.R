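## internal helpers

## run `expr` under a local RNG state seeded with `seed`, restoring the
## caller's .Random.seed afterwards so simulations do not perturb user code
withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("seed must be a single finite number", call. = FALSE)
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

stopIfNot <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
}

#' Centered moving average with truncated edges
#'
#' Smooths a series with a centered window of `round(width * fps)` frames,
#' forced odd. Near the edges the window is truncated to the frames that
#' exist (no padding), so the output has the same length as the input.
#'
#' @param x numeric vector.
#' @param width window width in seconds.
#' @param fps frames per second.
#' @return numeric vector, same length as `x`.
#' @export
movingAverage <- function(x, width, fps) {
  stopIfNot(width > 0 && fps > 0, "width and fps must be positive")
  w <- as.integer(round(width * fps))
  if (w < 1L) w <- 1L
  if (w %% 2L == 0L) w <- w + 1L
  h <- (w - 1L) %/% 2L
  n <- length(x)
  if (h == 0L) return(x)
  cs <- cumsum(c(0, x))
  i <- seq_len(n)
  lo <- pmax(1L, i - h)
  hi <- pmin(n, i + h)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

## Sidak family-wise correction: adjusted p = 1 - (1 - p)^m
sidakAdjust <- function(p) {
  m <- length(p)
  pmin(1, 1 - (1 - p)^m)
}

## population standard deviation
popSd <- function(x) {
  m <- mean(x)
  sqrt(mean((x - m)^2))
}
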