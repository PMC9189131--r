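## Independent brute-force oracles, written before the implementations they
## check and kept deliberately naive.

## Frame-by-frame run labelling: walk the trace, label every maximal
## quiescent run strictly longer than minSleep seconds as sleep, everything
## else as motion, then collect maximal runs of equal labels into bouts.
rleSegmentOracle <- function(active, fps, minSleep = 6) {
  n <- length(active)
  lab <- character(n)
  i <- 1L
  while (i <= n) {
    j <- i
    while (j < n && active[j + 1L] == active[i]) j <- j + 1L
    runLen <- j - i + 1L
    lab[i:j] <- if (!active[i] && runLen / fps > minSleep) "sleep"
                else "motion"
    i <- j + 1L
  }
  kinds <- character()
  starts <- integer()
  ends <- integer()
  i <- 1L
  while (i <= n) {
    j <- i
    while (j < n && lab[j + 1L] == lab[i]) j <- j + 1L
    kinds <- c(kinds, lab[i])
    starts <- c(starts, i - 1L)
    ends <- c(ends, j)
    i <- j + 1L
  }
  data.frame(
    kind = kinds, start = starts / fps, end = ends / fps,
    duration = (ends - starts) / fps,
    atEdge = starts == 0L | ends == n,
    stringsAsFactors = FALSE
  )
}

## random binary trace generator for fuzzing, biased toward long runs
randomActivityTrace <- function(n, pFlip = 0.05) {
  x <- logical(n)
  x[1L] <- runif(1) < 0.5
  for (i in 2:n) x[i] <- if (runif(1) < pFlip) !x[i - 1L] else x[i - 1L]
  x
}

## discrete closed-form window means for a ramp-then-decay latent signal:
## frames are the implementation-independent ground truth grid
rampDecayWindowMeans <- function(rampRate, decayTau, peak, window, fps) {
  dt <- 1 / fps
  w <- round(window * fps)
  ## pre window: the last w frames of the motion bout, values
  ## peak - rampRate*dt*(w-1) ... peak (arithmetic series)
  preMean <- peak - rampRate * dt * (w - 1) / 2
  ## post window: first w sleep frames, peak * q^k for k = 1..w (geometric)
  q <- exp(-dt / decayTau)
  postMean <- peak * q * (1 - q^w) / (w * (1 - q))
  c(pre = preMean, post = postMean)
}

## geometric-hazard latency median (in frames) for per-frame probability p
geometricMedianFrames <- function(p) ceiling(log(0.5) / log(1 - p))
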