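test_that("difference masks count super-threshold pixels and flag noisy frames", {
  a <- matrix(5000L, 64, 48)
  expect_error(differenceMask(a, matrix(0L, 10, 10)), "shape")

  dm <- differenceMask(a, a)
  expect_equal(dm@foregroundCount, 0L)
  expect_true(dm@evaluable)
  expect_true(all(dm@mask == 0L))

  # exactly 10 pixels differing by 2x the threshold; brute-force count
  b <- a
  idx <- cbind(seq(3, 48, by = 5), seq(2, 47, by = 5))
  b[idx] <- b[idx] + 2L * 1400L
  dm <- differenceMask(b, a, pixelThreshold = 1400L)
  brute <- sum(abs(b - a) > 1400L)
  expect_equal(dm@foregroundCount, 10L)
  expect_equal(dm@foregroundCount, brute)

  # a flicker frame with more than T = 14,000 super-threshold pixels
  flick <- matrix(0L, 640, 480)
  flick[seq_len(20000)] <- 3000L
  dm <- differenceMask(flick, matrix(0L, 640, 480))
  expect_equal(dm@foregroundCount, 20000L)
  expect_false(dm@evaluable)
})

test_that("Sobel edge enhancement matches a hand convolution", {
  sx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3)
  # constant image: no gradient anywhere
  expect_true(all(edgeEnhance(matrix(1L, 20, 20)) == 0L))

  # vertical step: oracle via explicit convolution in both directions
  # (replicate-padded, matching the no-gradient-at-the-frame-border rule)
  step <- matrix(0L, 20, 20); step[11:20, ] <- 1L
  p <- padReplicate(step)
  gx <- oracleConv3x3(p, sx)[2:21, 2:21]
  gy <- oracleConv3x3(p, t(sx))[2:21, 2:21]
  oracle <- (sqrt(gx^2 + gy^2) > 0) + 0L
  expect_identical(edgeEnhance(step), oracle)
  expect_true(all(edgeEnhance(step)[10:11, 5] == 1L))

  # horizontal step by symmetry
  hstep <- t(step)
  expect_identical(edgeEnhance(hstep), t(oracle))
})

test_that("majority fill keeps pixels whose 3x3 neighbourhood sum exceeds 5", {
  expect_true(all(majorityFill(matrix(0L, 10, 10)) == 0L))

  solid <- matrix(0L, 9, 9); solid[4:6, 4:6] <- 1L
  out <- majorityFill(solid)
  oracle <- (oracleConv3x3(solid, matrix(1, 3, 3)) > 5) + 0L
  expect_identical(out, oracle)
  expect_equal(out[5, 5], 1L)        # centre sum 9 > 5
  # survivors: centre plus the four edge-centres (sum 6); corners drop
  expect_equal(sum(out), sum(oracle))
  expect_equal(out[4, 4], 0L)        # corner sum 4

  lone <- matrix(0L, 9, 9); lone[5, 5] <- 1L
  expect_true(all(majorityFill(lone) == 0L))
})

test_that("consolidation fills closed boundaries into solid regions", {
  expect_equal(sum(consolidateMask(matrix(0L, 40, 40),
                                   matrix(0L, 40, 40))), 0L)

  ring <- matrix(0L, 60, 60)
  ring[20:40, 20] <- 1L; ring[20:40, 40] <- 1L
  ring[20, 20:40] <- 1L; ring[40, 20:40] <- 1L
  out <- consolidateMask(ring, ring)
  # flood-fill oracle: interior of the ring must be foreground
  expect_true(all(out[25:35, 25:35] == 1L))
  lbl <- EBImage::bwlabel(out)
  expect_equal(max(lbl), 1)
})

test_that("blob extraction enforces the component-size floor exactly", {
  img <- matrix(0L, 200, 100)
  img[1:34, 1:11] <- 1L          # 34 x 11 = 374 px component
  img[100:119, 41:60] <- 1L      # 20 x 20 = 400 px component
  blobs <- extractBlobs(img, minComponentSize = 375L)
  expect_equal(nrow(blobs), 1L)
  expect_equal(blobs$pixel_count, 400L)

  # boundary: exactly 375 is conserved
  img2 <- matrix(0L, 100, 100); img2[1:25, 1:15] <- 1L
  expect_equal(nrow(extractBlobs(img2, 375L)), 1L)

  expect_equal(nrow(extractBlobs(matrix(0L, 50, 50))), 0L)
})

test_that("blob centroids are the arithmetic mean of member pixels", {
  img <- matrix(0L, 300, 300)
  img[101:121, 101:121] <- 1L    # 21x21 square at 0-based (100,100)
  b <- extractBlobs(img, minComponentSize = 375L)
  expect_equal(b$pixel_count, 441L)
  expect_equal(b$cx, 110)
  expect_equal(b$cy, 110)
  expect_equal(c(b$bx, b$by, b$bw, b$bh), c(100, 100, 21, 21))
})

test_that("stationary scenes segment to zero blobs; moving squares to one", {
  sc <- trajectoryScript("still", shapeWidth = 40, shapeHeight = 40,
    path = data.frame(t_ms = 0, x_px = 320, y_px = 240, depth_mm = 2000))
  ren <- renderSequence(sc, duration_s = 1, noise_sd = 0, seed = 1)
  for (i in c(2, 15, 30)) {
    s <- segmentFramePair(irFrame(ren$frames, i - 1), irFrame(ren$frames, i))
    expect_equal(nrow(s$blobs), 0L)
  }

  mv <- movingSquareFixture()
  for (i in 2:nFrames(mv$frames)) {
    s <- segmentFramePair(irFrame(mv$frames, i - 1), irFrame(mv$frames, i))
    expect_equal(nrow(s$blobs), 1L)
    expect_gte(s$blobs$pixel_count, 375L)
  }
})

test_that("segmentation output is deterministic with raster-ordered labels", {
  mv <- movingSquareFixture()
  a <- segmentFramePair(irFrame(mv$frames, 4), irFrame(mv$frames, 5))
  b <- segmentFramePair(irFrame(mv$frames, 4), irFrame(mv$frames, 5))
  expect_identical(a$blobs, b$blobs)
  expect_equal(a$blobs$label, seq_len(nrow(a$blobs)))
})

test_that("pipeline blob centroid tracks the true object centroid closely", {
  fx <- slabFixture()
  errs <- c()
  for (i in 2:nFrames(fx$frames)) {
    s <- segmentFramePair(irFrame(fx$frames, i - 1), irFrame(fx$frames, i))
    expect_equal(nrow(s$blobs), 1L)
    # differencing straddles frames i-1 and i; compare to their midpoint
    tx <- (fx$truth$obj1$centroids$x_px[i - 1] +
             fx$truth$obj1$centroids$x_px[i]) / 2
    errs <- c(errs, abs(s$blobs$cx - tx),
              abs(s$blobs$cy - fx$truth$obj1$centroids$y_px[i]))
  }
  expect_lt(max(errs), 3)
})
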