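test_that("depth lookup grows its window and honours the 21x21 limit", {
  d <- matrix(0L, 100, 100)
  d[51, 51] <- 1700L
  expect_equal(depthLookup(d, c(50, 50)), 1700L)   # direct hit, window 1

  d[51, 51] <- 0L
  d[52, 52] <- 1850L
  expect_equal(depthLookup(d, c(50, 50)), 1850L)   # offset (1,1), window 3

  # nearest nonzero wins: value at distance 2 vs distance 5
  d2 <- matrix(0L, 100, 100)
  d2[53, 51] <- 2222L; d2[56, 51] <- 3333L
  expect_equal(depthLookup(d2, c(50, 50)), 2222L)

  # all zeros within 21x21 -> missing
  d3 <- matrix(0L, 100, 100); d3[80, 80] <- 900L
  expect_true(is.na(depthLookup(d3, c(50, 50))))
  expect_error(depthLookup(d3, c(200, 50)), "outside")
})

test_that("a single moving object yields one track spanning all frames", {
  path <- data.frame(frame = 1:60, cx = 100 + 2 * (1:60), cy = 240)
  ts <- associateTracks(makeBlobFrames(list(path), 60))
  expect_equal(length(trackIds(ts)), 1L)
  expect_equal(nrow(trackData(ts)[[1]]), 60L)
})

test_that("two parallel objects keep distinct ids with no swaps", {
  p1 <- data.frame(frame = 1:60, cx = 100 + 2 * (1:60), cy = 100)
  p2 <- data.frame(frame = 1:60, cx = 100 + 2 * (1:60), cy = 300)
  ts <- associateTracks(makeBlobFrames(list(p1, p2), 60))
  expect_equal(length(trackIds(ts)), 2L)
  for (tr in trackData(ts)) {
    expect_equal(nrow(tr), 60L)
    expect_equal(length(unique(tr$cy_raw)), 1L)    # never jumps rows
  }
})

test_that("tracks closed after a long gap reopen under a fresh id", {
  seen <- c(1:20, 45:60)    # 24-frame gap > 15-frame timeout
  path <- data.frame(frame = seen, cx = 200, cy = 200)
  ts <- associateTracks(makeBlobFrames(list(path), 60))
  expect_equal(length(trackIds(ts)), 2L)
  expect_equal(sum(vapply(trackData(ts), nrow, integer(1))), 36L)
})

test_that("Kalman smoothing converges on an exact constant-velocity path", {
  path <- data.frame(frame = 1:90, cx = 50 + 3 * (1:90), cy = 100 + (1:90))
  ts <- associateTracks(makeBlobFrames(list(path), 90))
  tr <- trackData(ts)[[1]]
  resid <- sqrt((tr$cx - tr$cx_raw)^2 + (tr$cy - tr$cy_raw)^2)
  expect_lt(max(resid[16:90]), 1)                  # < 1 px after burn-in
  # residual decays monotonically in the steady state (averaged)
  expect_lt(mean(resid[46:90]), mean(resid[16:45]))
})

test_that("child-track whitelisting merges ids and warns on absent ones", {
  p1 <- data.frame(frame = 1:20, cx = 100, cy = 100)
  p3 <- data.frame(frame = 40:60, cx = 105, cy = 100)
  p2 <- data.frame(frame = 1:60, cx = 400, cy = 300)
  ts <- associateTracks(makeBlobFrames(list(p1, p2, p3), 60))
  expect_equal(length(trackIds(ts)), 3L)

  only1 <- selectChildTracks(ts, "1")
  expect_equal(nrow(only1), 20L)

  merged <- selectChildTracks(ts, c("1", "3"))
  expect_equal(nrow(merged), 41L)
  expect_false(is.unsorted(merged$timestamp_ms))

  expect_warning(out <- selectChildTracks(ts, "9"), "not present")
  expect_equal(nrow(out), 0L)
})

test_that("end-to-end track count matches the scripted objects", {
  fx <- slabFixture()
  ts <- extractTracks(fx$frames)
  expect_equal(length(trackIds(ts)), 1L)
  tr <- trackData(ts)[[1]]
  expect_equal(nrow(tr), nFrames(fx$frames) - 1L)
  expect_true(all(tr$ir == 30000L))
  expect_true(all(tr$depth_mm == 3000L))
})
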