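test_that("single-run and boundary traces segment as hand-computed", {
  ## all-active 100 s: one motion bout touching both edges
  s <- segmentBouts(rep(TRUE, 1000), fps = 10)
  b <- bouts(s)
  expect_identical(nrow(b), 1L)
  expect_identical(b$kind, "motion")
  expect_equal(c(b$start, b$end), c(0, 100))
  expect_true(b$atEdge)

  ## a 60-frame (exactly 6.0 s) quiescent run at 10 fps is NOT a sleep
  ## bout under the strictly-longer-than rule: one single motion bout
  tr <- c(rep(TRUE, 100), rep(FALSE, 60), rep(TRUE, 100))
  b6 <- bouts(segmentBouts(tr, fps = 10, minSleepDuration = 6))
  expect_identical(nrow(b6), 1L)
  expect_identical(b6$kind, "motion")

  ## one frame more (6.1 s) and it is a sleep bout
  tr61 <- c(rep(TRUE, 100), rep(FALSE, 61), rep(TRUE, 100))
  b61 <- bouts(segmentBouts(tr61, fps = 10, minSleepDuration = 6))
  expect_identical(b61$kind, c("motion", "sleep", "motion"))
  expect_equal(b61$duration[2], 6.1)

  expect_error(segmentBouts(logical(0), fps = 10), "non-empty")
})

test_that("segmentation equals the brute-force RLE oracle on random traces", {
  set.seed(101)
  for (rep in 1:200) {
    n <- sample(50:2000, 1)
    fr <- sample(c(2, 6.67, 10), 1)
    tr <- randomActivityTrace(n, pFlip = runif(1, 0.01, 0.2))
    got <- bouts(segmentBouts(tr, fps = fr))
    want <- rleSegmentOracle(tr, fr)
    expect_equal(got, want)
  }
})

test_that("partition, alternation and idempotence invariants hold", {
  set.seed(202)
  for (rep in 1:100) {
    n <- sample(50:3000, 1)
    fr <- sample(c(2, 6.67, 10), 1)
    tr <- randomActivityTrace(n, pFlip = runif(1, 0.01, 0.3))
    s <- segmentBouts(tr, fps = fr)
    b <- bouts(s)
    expect_equal(sum(b$duration), n / fr, tolerance = 1e-9)
    if (nrow(b) > 1)
      expect_true(all(b$kind[-1] != b$kind[-nrow(b)]))
    ## idempotence: re-segment the reconstructed state
    s2 <- segmentBouts(stateVector(s), fps = fr,
                       minSleepDuration = s@minSleepDuration)
    expect_equal(bouts(s2), b)
  }
})

test_that("raising minSleepDuration never adds sleep bouts", {
  set.seed(303)
  for (rep in 1:30) {
    tr <- randomActivityTrace(1500, pFlip = 0.1)
    counts <- vapply(c(2, 4, 6, 8), function(ms)
      sum(bouts(segmentBouts(tr, fps = 10, minSleepDuration = ms))$kind ==
            "sleep"), numeric(1))
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("bout filtering follows the strict 12-s and edge rules", {
  ## synthetic series with inner durations 12, 5, 30, 13 s (plus edge bouts)
  mk <- rep(c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE),
            round(c(20, 12, 5, 30, 13, 20) * 10))
  s <- segmentBouts(mk, fps = 10)
  b <- bouts(s)
  inner <- b[!b$atEdge, ]
  expect_setequal(inner$duration, c(12, 5, 30, 13))

  kept <- filterBouts(s, minDuration = 12, dropEdges = TRUE)
  expect_setequal(kept$duration, c(13, 30))
  keptIncl <- filterBouts(s, minDuration = 12, dropEdges = TRUE,
                          inclusive = TRUE)
  expect_setequal(keptIncl$duration, c(12, 13, 30))

  ## two-bout recording: everything touches an edge
  two <- segmentBouts(rep(c(TRUE, FALSE), c(100, 100)), fps = 10)
  expect_identical(nrow(filterBouts(two, minDuration = 0)), 0L)

  ## no-op filter
  expect_equal(filterBouts(s, minDuration = 0, dropEdges = FALSE), b)
})

test_that("fraction of quiescence is exact on hand-countable traces", {
  allQ <- fractionOfQuiescence(rep(FALSE, 600), fps = 10, window = 10)
  expect_true(all(allQ$fraction == 1))
  allA <- fractionOfQuiescence(rep(TRUE, 600), fps = 10, window = 10)
  expect_true(all(allA$fraction == 0))

  alt <- fractionOfQuiescence(rep(c(TRUE, FALSE), 300), fps = 10,
                              window = 2)
  expect_true(all(alt$fraction == 0.5))

  ## trailing partial window reported with its own length
  part <- fractionOfQuiescence(rep(FALSE, 25), fps = 10, window = 1)
  expect_identical(part$n_frames, c(10L, 10L, 5L))
  expect_equal(part$window_start_s, c(0, 1, 2))

  expect_error(fractionOfQuiescence(rep(TRUE, 10), fps = 10,
                                    window = 0.01), "one frame")
})

test_that("lethargus detection returns the hand-identified block", {
  mkQ <- function(fracs, window = 60, fps = 10) {
    act <- unlist(lapply(fracs, function(f)
      rep(c(FALSE, TRUE), round(c(f, 1 - f) * window * fps))))
    fractionOfQuiescence(act, fps = fps, window = window)
  }

  ## never quiescent: nothing detected
  expect_null(detectLethargus(mkQ(rep(0, 30)), minSpan = 60))

  ## one block at fraction 0.6 flanked by zeros
  q <- mkQ(c(rep(0, 10), rep(0.6, 12), rep(0, 10)))
  got <- detectLethargus(q, enterThreshold = 0.05, exitThreshold = 0.05,
                         minSpan = 600)
  expect_equal(got$start, 600)
  expect_equal(got$end, 600 + 12 * 60)

  ## degenerate threshold 0: the entire recording
  all0 <- detectLethargus(mkQ(rep(0, 30)), enterThreshold = 0,
                          exitThreshold = 0, minSpan = 60)
  expect_equal(all0$start, 0)
  expect_equal(all0$end, 30 * 60)

  expect_error(detectLethargus(q, enterThreshold = 1.2), "0, 1")
})
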