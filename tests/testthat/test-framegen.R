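test_that("a stationary object renders identical frames and zero velocity", {
  sc <- trajectoryScript("still", shapeWidth = 40, shapeHeight = 40,
    path = data.frame(t_ms = 0, x_px = 320, y_px = 240, depth_mm = 2000))
  ren <- renderSequence(sc, duration_s = 2, noise_sd = 0, seed = 1)
  expect_equal(nFrames(ren$frames), 60L)
  for (i in 2:60)
    expect_identical(irFrame(ren$frames, i), irFrame(ren$frames, 1))
  vel <- ren$truth$still$velocity
  expect_true(all(vel$v_mps == 0))
  expect_true(all(ren$truth$still$cars$code == 1L))
})

test_that("rendered mask centroid follows the scripted position", {
  sc <- trajectoryScript("sq", shapeWidth = 40, shapeHeight = 40,
    path = data.frame(t_ms = c(0, 1000), x_px = c(100, 160), y_px = 240,
                      depth_mm = 2000))
  ren <- renderSequence(sc, duration_s = 1, noise_sd = 0, seed = 1)
  # object pixels are the only ones at the scripted intensity
  cents <- sapply(seq_len(30), function(k) {
    idx <- which(irFrame(ren$frames, k) == 30000, arr.ind = TRUE)
    colMeans(idx) - 1   # 0-based
  })
  truth <- ren$truth$sq$centroids
  expect_lt(max(abs(cents[1, ] - truth$x_px)), 0.5 + 1e-9)
  expect_lt(max(abs(cents[2, ] - truth$y_px)), 0.5 + 1e-9)
  # +2 px/frame scripted motion shows up as ~2 px mask displacement
  d <- diff(cents[1, ])
  expect_true(all(abs(d - 2) <= 0.5))
})

test_that("depth dropout spans zero the object depth pixels", {
  sc <- trajectoryScript("sq", shapeWidth = 40, shapeHeight = 40,
    path = data.frame(t_ms = 0, x_px = 320, y_px = 240, depth_mm = 1850),
    dropoutSpans = data.frame(start_ms = 3000, end_ms = 4000))
  ren <- renderSequence(sc, duration_s = 5, noise_sd = 0, seed = 1)
  inside <- function(k) depthFrame(ren$frames, k)[301:340, 221:260]
  expect_true(all(inside(30) == 1850))       # t ~ 967 ms
  expect_true(all(inside(100) == 0))         # t = 3300 ms, inside span
  expect_true(all(inside(140) == 1850))      # t = 4633 ms, after span
})

test_that("rendering is bit-identical under a fixed seed", {
  sc <- trajectoryScript("sq", shapeWidth = 30, shapeHeight = 30,
    path = data.frame(t_ms = c(0, 1000), x_px = c(200, 260), y_px = 200,
                      depth_mm = 2500))
  a <- renderSequence(sc, 1, noise_sd = 150, seed = 7)
  b <- renderSequence(sc, 1, noise_sd = 150, seed = 7)
  expect_identical(a$frames@infrared, b$frames@infrared)
  expect_identical(a$frames@depth, b$frames@depth)
  c <- renderSequence(sc, 1, noise_sd = 150, seed = 8)
  expect_false(identical(a$frames@infrared, c$frames@infrared))
})

test_that("frame count is exactly floor(duration * 30)", {
  sc <- trajectoryScript("sq",
    path = data.frame(t_ms = 0, x_px = 320, y_px = 240, depth_mm = 2000))
  expect_equal(nFrames(renderSequence(sc, 1.97, 0, 1)$frames), 59L)
  expect_equal(nFrames(renderSequence(sc, 0.5, 0, 1)$frames), 15L)
})

test_that("paths leaving the frame raise an error naming the time", {
  sc <- trajectoryScript("sq", shapeWidth = 40, shapeHeight = 40,
    path = data.frame(t_ms = c(0, 1000), x_px = c(600, 639), y_px = 240,
                      depth_mm = 2000))
  expect_error(renderSequence(sc, 1, 0, 1), "t = ")
  expect_error(
    trajectoryScript("bad",
      path = data.frame(t_ms = 0, x_px = 700, y_px = 240, depth_mm = 2000)),
    "0 <= x < 640")
})

test_that("ground-truth CARS codes reflect scripted speed", {
  cal <- canonicalCalibration()
  fast <- makeConstantVelocityScript(2.0, "x", depth_mm = 3800,
                                     duration_s = 2)
  slow <- makeConstantVelocityScript(0.8, "x", depth_mm = 3800,
                                     duration_s = 2)
  expect_true(all(renderSequence(fast, 2, 0, 1)$truth$obj1$cars$code == 4L))
  expect_true(all(renderSequence(slow, 2, 0, 1)$truth$obj1$cars$code == 3L))
})
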