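test_that("bout-aligned averaging matches hand assembly", {
  ## identical bouts with identical traces: mean is the trace, SEM 0
  seg <- replicate(5, sin(seq(0, 2, length.out = 50)), simplify = FALSE)
  avg <- alignAndAverage(seg, fps = 10, minSamples = 0)
  expect_equal(avg$mean, seg[[1]])
  expect_true(all(avg$sem == 0))
  expect_true(all(avg$n == 5))

  ## two bouts of 20 s and 30 s at minSamples = 1: output extends to 30 s
  ## with n dropping from 2 to 1 at 20 s
  segs <- list(rep(1, 200), rep(3, 300))
  a <- alignAndAverage(segs, fps = 10, minSamples = 0)
  expect_identical(nrow(a), 300L)
  expect_equal(a$n, c(rep(2L, 200), rep(1L, 100)))
  expect_equal(a$mean, c(rep(2, 200), rep(3, 100)))
  expect_true(all(is.na(a$sem[201:300])))
  a1 <- alignAndAverage(segs, fps = 10, minSamples = 1)
  expect_identical(nrow(a1), 200L)

  ## threshold saturation: n = 10 <= minSamples = 10 is dropped everywhere
  ten <- replicate(10, rnorm(40), simplify = FALSE)
  expect_identical(nrow(alignAndAverage(ten, fps = 10, minSamples = 10)),
                   0L)
})

test_that("alignAndAverage at minSamples = 0 conserves per-point counts", {
  set.seed(61)
  lens <- sample(5:60, 20, replace = TRUE)
  segs <- lapply(lens, rnorm)
  a <- alignAndAverage(segs, fps = 10, minSamples = 0)
  for (t in seq_len(max(lens)))
    expect_identical(a$n[t], sum(lens >= t))
})

test_that("normalized profiles reproduce closed-form quartile means", {
  ## constant trace: flat profile, Q1 = Q4
  flat <- replicate(6, rep(2.5, 30), simplify = FALSE)
  pf <- normalizedProfile(flat)
  expect_true(all(pf$profile$mean == 2.5))
  expect_equal(pf$perBout$q1, pf$perBout$q4)

  ## exact linear ramp 0 -> 1: profile is the identity on the midpoint
  ## grid; continuous quartile means are 0.125 and 0.875, so Q4 - Q1 = 0.75
  ramp <- lapply(c(20, 35, 50), function(n) seq(0, 1, length.out = n))
  pr <- normalizedProfile(ramp, gridSize = 100)
  expect_equal(pr$profile$mean, pr$profile$grid, tolerance = 1e-12)
  expect_equal(pr$perBout$q1, rep(0.125, 3), tolerance = 1e-12)
  expect_equal(pr$perBout$q4, rep(0.875, 3), tolerance = 1e-12)
  expect_equal(pr$perBout$q4 - pr$perBout$q1, rep(0.75, 3),
               tolerance = 1e-12)

  ## bouts shorter than 2 frames are skipped with a warning
  expect_warning(normalizedProfile(list(1, seq(0, 1, length.out = 10))),
                 "skipped")
})

test_that("normalized profiles are invariant to monotone time warping", {
  ## same underlying shape sampled at very different frame counts: the
  ## resampled profiles agree at grid resolution (the operation's purpose)
  shape <- function(u) u^2
  a <- shape(seq(0, 1, length.out = 40))
  b <- shape(seq(0, 1, length.out = 400))
  pa <- normalizedProfile(list(a), gridSize = 50)
  pb <- normalizedProfile(list(b), gridSize = 50)
  expect_equal(pa$profile$mean, pb$profile$mean, tolerance = 5e-3)
})

test_that("transition windows match closed-form ramp/decay means", {
  ## build a noise-free ramp-then-decay latent trace on an exact schedule
  fps <- 10
  rampRate <- 0.05
  tau <- 3
  sch <- simulateBoutSchedule(
    totalDuration = 400, fps = fps, motionMean = 40, motionSdlog = 0.3,
    sleepBase = 25, homeostaticGain = 0, sleepNoiseSd = 0, seed = 17
  )
  tr <- simulateCalcium(sch, rampRate = rampRate, decayTau = tau,
                        channelNoiseSd = 0, seed = 17)
  series <- segmentBouts(trueState(sch), fps)
  ev <- transitionTriggered(tr$latent, series, kind = "MS", window = 12)
  expect_gt(nrow(ev), 0)

  b <- bouts(series)
  for (k in seq_len(nrow(ev))) {
    i <- which(abs(b$end - ev$time_s[k]) < 1e-9 & b$kind == "motion")
    peak <- tr$latent[round(b$end[i] * fps)]
    want <- rampDecayWindowMeans(rampRate, tau, peak, 12, fps)
    expect_equal(ev$preMean[k], unname(want["pre"]), tolerance = 1e-6)
    expect_equal(ev$postMean[k], unname(want["post"]), tolerance = 1e-6)
    expect_lt(ev$postMean[k], ev$preMean[k])
  }

  ## constant trace: pre equals post for every event
  const <- rep(1.5, length(tr$latent))
  evc <- transitionTriggered(const, series, kind = "MS", window = 12)
  expect_equal(evc$preMean, evc$postMean)

  ## a trace symmetric about each transition gives equal window means
  sym <- abs(seq_along(const) - round(ev$time_s[1] * fps) - 0.5)
  evs <- transitionTriggered(sym, series, kind = "MS", window = 12)
  expect_equal(evs$preMean[1], evs$postMean[1])
})

test_that("SM transitions under the generative model center near zero", {
  ## ramp restarts from a low baseline after each sleep bout, so the
  ## paired SM pre/post difference is small relative to the MS drop
  fps <- 10
  sch <- simulateBoutSchedule(
    totalDuration = 2400, fps = fps, motionMean = 40, sleepBase = 25,
    homeostaticGain = 0, sleepNoiseSd = 0, seed = 19
  )
  tr <- simulateCalcium(sch, channelNoiseSd = 0, seed = 19)
  series <- segmentBouts(trueState(sch), fps)
  sm <- transitionTriggered(tr$latent, series, kind = "SM", window = 12)
  ms <- transitionTriggered(tr$latent, series, kind = "MS", window = 12)
  dSM <- mean(sm$postMean - sm$preMean)
  dMS <- mean(ms$postMean - ms$preMean)
  expect_lt(abs(dSM), abs(dMS) / 3)
  expect_lt(dMS, 0)
})

test_that("peak-latency regression recovers the generator algebra", {
  ## all bouts identical: zero variance in both coordinates, regression
  ## reported as undefined
  same <- replicate(5, c(1, 2, 3, 2, 1), simplify = FALSE)
  deg <- peakLatencyCorrelation(same, fps = 10)
  expect_true(is.na(deg$slope))
  expect_null(deg$fit)
  expect_identical(nrow(deg$peaks), 5L)

  ## noise-free linear ramps of different lengths: slope = rampRate,
  ## r = 1 (the truncated smoothing window shifts every peak by the same
  ## constant, leaving slope and correlation exact)
  fps <- 10
  rate <- 0.05
  ramps <- lapply(c(150, 200, 300, 420), function(n)
    rate * (seq_len(n)) / fps)
  res <- peakLatencyCorrelation(ramps, fps = fps, smooth = 1)
  expect_equal(res$slope, rate, tolerance = 1e-9)
  expect_equal(res$r, 1, tolerance = 1e-9)
  ## peaks land on the final frame of each ramp
  expect_equal(res$peaks$latency_s, c(149, 199, 299, 419) / fps)

  ## ties resolve to the earliest frame
  tied <- list(c(0, 5, 5, 5, 0, 0, 0, 0, 0, 0, 0))
  pt <- peakLatencyCorrelation(tied, fps = 1, smooth = 1)
  expect_equal(pt$peaks$latency_s, 1)
})

test_that("cumulative locomotor activity is linear for constant rates", {
  series <- segmentBouts(rep(c(TRUE, FALSE, TRUE), c(300, 100, 300)),
                         fps = 10)
  cp <- rep(120, 700)
  res <- cumulativeLocomotor(cp, series, fps = 10)
  expect_length(res$curves, 2)
  expect_equal(res$r2, c(1, 1), tolerance = 1e-12)
  expect_equal(res$curves[[1]]$cumulative, 120 * (1:300))

  zero <- cumulativeLocomotor(rep(0, 700), series, fps = 10)
  expect_true(all(zero$curves[[1]]$cumulative == 0))
  expect_true(all(is.na(zero$r2)))
})

test_that("moving average matches a brute-force windowed mean", {
  set.seed(71)
  x <- rnorm(200)
  got <- movingAverage(x, width = 1, fps = 10)  # 11-frame window
  want <- sapply(seq_along(x), function(i)
    mean(x[max(1, i - 5):min(200, i + 5)]))
  expect_equal(got, want)
})
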