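test_that("noise-free schedules have fixed sleep durations and tile exactly", {
  sch <- simulateBoutSchedule(
    totalDuration = 600, fps = 10, motionMean = 30,
    homeostaticGain = 0, sleepNoiseSd = 0, sleepBase = 20,
    minBout = 7, seed = 11
  )
  b <- bouts(sch)
  inner <- b$kind == "sleep" & b$end < totalDuration(sch)
  expect_true(all(abs(b$duration[inner] - 20) < 1e-9))

  expect_length(trueState(sch), 6000L)
  expect_equal(sum(b$duration), 600)
  expect_equal(b$start[1], 0)
  expect_true(all(b$kind[-1] != b$kind[-nrow(b)]))
  expect_identical(b$kind[1], "motion")
})

test_that("schedules are seed-reproducible and seed-sensitive", {
  a <- simulateBoutSchedule(seed = 5)
  b <- simulateBoutSchedule(seed = 5)
  c <- simulateBoutSchedule(seed = 6)
  expect_identical(bouts(a), bouts(b))
  expect_identical(trueState(a), trueState(b))
  expect_false(identical(bouts(a), bouts(c)))
})

test_that("OLS on generator output recovers the homeostatic gain", {
  ## oracle: regression on the generator's own (prior motion, sleep) pairs,
  ## read straight from the bout table before any pipeline runs
  sch <- simulateBoutSchedule(
    totalDuration = 11500, fps = 2, motionMean = 30,
    homeostaticGain = 0.5, sleepNoiseSd = 2, seed = 21
  )
  b <- bouts(sch)
  i <- which(b$kind == "sleep" & b$end < totalDuration(sch))
  i <- i[i > 1]
  expect_gt(length(i), 150)
  fit <- lm(b$duration[i] ~ b$duration[i - 1])
  est <- coef(fit)[2]
  se <- summary(fit)$coefficients[2, 2]
  expect_true(est - 1.96 * se <= 0.5 && 0.5 <= est + 1.96 * se)
})

test_that("invalid schedule configurations are rejected", {
  expect_error(simulateBoutSchedule(totalDuration = -1), "positive")
  expect_error(simulateBoutSchedule(fps = 0), "positive")
  expect_error(simulateBoutSchedule(motionMean = 0), "positive")
  expect_error(simulateBoutSchedule(sleepNoiseSd = -1), "non-negative")
})

test_that("noise-free latent calcium matches its closed forms", {
  sch <- simulateBoutSchedule(
    totalDuration = 100, fps = 10, motionMean = 20,
    homeostaticGain = 0, sleepNoiseSd = 0, sleepBase = 15, seed = 3
  )
  tr <- simulateCalcium(sch, rampRate = 0.05, decayTau = 3,
                        channelNoiseSd = 0, seed = 3)
  b <- bouts(sch)
  st <- trueState(sch)

  ## hand integration for the first 3 frames (motion): C = r*dt*(1:3)
  expect_equal(tr$latent[1:3], 0.05 * 0.1 * (1:3))

  ## over a full motion run of L frames C rises by exactly rampRate * L/fps
  r <- rle(st)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  k <- which(r$values)[2]  # an inner motion run
  rise <- tr$latent[ends[k]] - tr$latent[starts[k] - 1L]
  expect_equal(rise, 0.05 * r$lengths[k] / 10, tolerance = 1e-9)

  ## sleep decay: C after t seconds is c0 * exp(-t / tau)
  sl <- b[b$kind == "sleep" & b$end < 100, ][1, ]
  j0 <- round(sl$start * 10) + 1
  c0 <- tr$latent[j0 - 1]
  k <- 20  # 2 s into the bout
  expect_equal(tr$latent[j0 + k - 1], c0 * exp(-k * 0.1 / 3),
               tolerance = 1e-9)

  ## peak latent within each motion bout falls on its final frame
  for (r in which(b$kind == "motion" & b$end < 100)) {
    i0 <- round(b$start[r] * 10) + 1
    i1 <- round(b$end[r] * 10)
    expect_equal(which.max(tr$latent[i0:i1]), i1 - i0 + 1)
  }

  ## zero ramp, zero noise: GCaMP constant at baseline
  flat <- simulateCalcium(sch, rampRate = 0, channelNoiseSd = 0, seed = 1)
  expect_true(all(flat$gcamp == 100))
  expect_true(all(flat$rfp == 200))
})

test_that("rendered video honours the static and guaranteed-motion cases", {
  sch <- simulateBoutSchedule(totalDuration = 5, fps = 10, seed = 2)

  ## static scene: zero jitter and zero noise -> identical frames
  still <- renderVideo(sch, jitterPx = 0, pixelNoiseSd = 0,
                       emptyFrames = 5, seed = 2)
  n <- dim(still$stack)[3]
  for (t in 2:n)
    expect_identical(still$stack[, , t], still$stack[, , t - 1])

  ## all-motion schedule with jitter >= 2 and no noise: every subtracted
  ## frame has at least one changed pixel
  allMotion <- simulateBoutSchedule(
    totalDuration = 5, fps = 10, motionMean = 1000, motionSdlog = 0,
    seed = 2
  )
  expect_true(all(trueState(allMotion)))
  vid <- renderVideo(allMotion, jitterPx = 2, pixelNoiseSd = 0,
                     emptyFrames = 5, seed = 2)
  for (t in 2:dim(vid$stack)[3])
    expect_gt(sum(vid$stack[, , t] != vid$stack[, , t - 1]), 0)

  ## blob area is exactly wormArea and the centre stays inside the frame
  expect_equal(sum(still$stack[, , 1] > 100), 600)
  expect_true(all(still$positions >= 1 &
                    still$positions <= 64))
})

test_that("video rendering is reproducible under a fixed seed", {
  sch <- simulateBoutSchedule(totalDuration = 4, fps = 10, seed = 9)
  a <- renderVideo(sch, emptyFrames = 4, seed = 42)
  b <- renderVideo(sch, emptyFrames = 4, seed = 42)
  expect_identical(a$stack, b$stack)
  expect_identical(a$empty, b$empty)
})

test_that("optogenetic hazard simulation matches the geometric law", {
  ## hazard 1 per second: certain transition at the first frame
  ex <- simulateOptogenetics(nTrials = 20, baselineHazard = 1,
                             stimHazardMultiplier = 1, fps = 2, seed = 8)
  expect_true(all(trials(ex)$latency == 0.5))

  ## multiplier 4 within a 10-s window shortens treated latencies; the
  ## oracle is the analytic geometric-hazard median
  ex2 <- simulateOptogenetics(nTrials = 400, baselineHazard = 0.1,
                              stimHazardMultiplier = 4,
                              stimEffectWindow = 10, fps = 2, seed = 8)
  tr <- trials(ex2)
  medT <- median(tr$latency[tr$group == "treated"], na.rm = TRUE)
  medC <- median(tr$latency[tr$group == "control"], na.rm = TRUE)
  expect_lt(medT, medC)
  pC <- 1 - (1 - 0.1)^(1 / 2)
  pT <- 1 - (1 - 0.1)^(4 / 2)
  expect_equal(medC, geometricMedianFrames(pC) / 2, tolerance = 0.35)
  expect_equal(medT, geometricMedianFrames(pT) / 2, tolerance = 0.35)

  ## null effect: the two groups share one latency law
  ex3 <- simulateOptogenetics(nTrials = 1000, baselineHazard = 0.2,
                              stimHazardMultiplier = 1, fps = 2, seed = 8)
  t3 <- trials(ex3)
  m <- tapply(t3$latency, t3$group, median, na.rm = TRUE)
  expect_equal(unname(m["treated"]), unname(m["control"]),
               tolerance = 0.51)
})
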