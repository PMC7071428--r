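test_that("calibration fitting recovers the generating line exactly", {
  d <- seq(1000, 4000, by = 250)
  obs <- data.frame(depth_mm = d,
                    px_height = 1.75 / (1.5e-6 * d + 6.4e-4))
  cal <- fitCalibration(obs, trueHeight_m = 1.75)
  co <- calibrationCoef(cal)
  expect_lt(abs(co["slope"] - 1.5e-6) / 1.5e-6, 1e-10)
  expect_lt(abs(co["intercept"] - 6.4e-4) / 6.4e-4, 1e-10)

  # two exact points define the line
  cal2 <- fitCalibration(obs[c(1, 13), ])
  expect_equal(unname(calibrationCoef(cal2)["slope"]), 1.5e-6,
               tolerance = 1e-10)

  expect_error(fitCalibration(data.frame(depth_mm = c(2000, 2000),
                                         px_height = c(100, 100))),
               "two distinct depths")
  expect_error(fitCalibration(data.frame(depth_mm = c(1000, 2000),
                                         px_height = c(-1, 100))),
               "positive")
})

test_that("noisy calibration observations stay within 5% of the truth", {
  set.seed(11)
  d <- runif(50, 1000, 4000)
  hpx <- 1.75 / (1.5e-6 * d + 6.4e-4) * (1 + rnorm(50, 0, 0.01))
  cal <- fitCalibration(data.frame(depth_mm = d, px_height = hpx))
  co <- calibrationCoef(cal)
  expect_lt(abs(co["slope"] - 1.5e-6) / 1.5e-6, 0.05)
  expect_lt(abs(co["intercept"] - 6.4e-4) / 6.4e-4, 0.05)
})

test_that("the Fourier estimator matches motion scripted per window", {
  vmaxf <- 120 / 30   # 4 px/frame expected maximum
  # stationary: DC-only spectrum, zero velocity
  v <- fourierVelocity(rep(100, 30), 30000, vMaxAxisPerFrame = vmaxf)
  expect_equal(as.numeric(v), 0)
  expect_equal(attr(v, "peak_bin"), 0L)

  # +2 px/frame: 60 px per 30 frames within 1 px of the oracle
  pos <- 100 + 2 * (0:29)
  v <- fourierVelocity(pos, 30000, vMaxAxisPerFrame = vmaxf)
  expect_lt(abs(as.numeric(v) - 60 / 30 * 30), 1)
  expect_lt(abs(as.numeric(v) - oracleFiniteDiff(pos)), 1)

  # mirrored motion: same magnitude, opposite sign
  vr <- fourierVelocity(rev(pos), 30000, vMaxAxisPerFrame = vmaxf)
  expect_equal(as.numeric(vr), -as.numeric(v), tolerance = 1e-9)

  # rounded (rasterised) positions still agree with the oracle
  pos2 <- round(100 + 1.3 * (0:29))
  v2 <- fourierVelocity(pos2, 30000, vMaxAxisPerFrame = vmaxf)
  expect_lt(abs(as.numeric(v2) - oracleFiniteDiff(pos2)), 1)

  # > 50% missing -> missing sample
  posNA <- pos; posNA[1:16] <- NA
  expect_true(is.na(fourierVelocity(posNA, 30000,
                                    vMaxAxisPerFrame = vmaxf)))
})

test_that("velocity-to-m/s conversion applies the depth scaling", {
  cal <- canonicalCalibration()
  expect_equal(scalingAt(cal, 0), 6.4e-4)
  expect_equal(toMps(60, 2400, cal, "x"),
               60 * (1.5e-6 * 2400 + 6.4e-4))
  expect_equal(toMps(0, 3000, cal, "y"), 0)
  expect_true(is.na(toMps(60, NA, cal, "x")))
  expect_true(is.na(toMps(NA, 2000, cal, "x")))
  # z is metric already
  expect_equal(toMps(1500, NA, cal, "z"), 1.5)
  # clipping at the plane maximum
  expect_warning(v <- toMps(1e5, 4000, cal, "x"), "clipped")
  expect_equal(v, 4)
})

test_that("accelerations are first differences in g with gap propagation", {
  expect_equal(accelerations(c(1, 1, 1, 1)), rep(0, 4))
  expect_equal(accelerations(c(0, 0.980665))[2], 0.1)
  up <- accelerations(c(0, 1, 2)); dn <- accelerations(c(2, 1, 0))
  expect_equal(up[-1], -dn[-1])
  a <- accelerations(c(1, NA, 2, 2))
  expect_true(is.na(a[2]) && is.na(a[3]))
  expect_equal(a[4], 0)
})

test_that("vector-magnitude epochs aggregate per-second VM values", {
  # all-zero accelerations
  z <- rep(0, 10)
  ep <- vmEpochs(z, z, z)
  expect_equal(ep$vm_value, c(0, 0))

  # one second with a 3-4-5 triple (in g/1000 units)
  ax <- c(0.003, rep(0, 4)); ay <- c(0.004, rep(0, 4)); az <- rep(0, 5)
  ep <- vmEpochs(ax, ay, az, statistic = "mean")
  expect_equal(ep$vm_value, 1.0)   # per-second VM 5.0, mean over 5 s
  expect_equal(vmEpochs(ax, ay, az, statistic = "sum")$vm_value, 5.0)

  # >= 3 missing seconds -> missing epoch
  ep <- vmEpochs(c(NA, NA, NA, 0, 0), rep(0, 5), rep(0, 5))
  expect_true(is.na(ep$vm_value))
  expect_equal(ep$n_valid_seconds, 2L)

  # VM invariant to axis permutation and sign flips
  set.seed(3)
  a <- rnorm(10); b <- rnorm(10); c <- rnorm(10)
  expect_equal(vmEpochs(a, b, c)$vm_value, vmEpochs(c, a, b)$vm_value)
  expect_equal(vmEpochs(a, b, c)$vm_value, vmEpochs(-a, b, -c)$vm_value)
})

test_that("rendered constant-velocity fixtures recover scripted speeds", {
  # one plane each at a representative speed; the acceptance suite sweeps
  # the full grid
  cases <- list(list(v = 1.5, plane = "x"), list(v = 1.0, plane = "y"))
  for (cs in cases) {
    sc <- makeConstantVelocityScript(cs$v, cs$plane, depth_mm = 3800,
                                     duration_s = 3)
    ren <- renderSequence(sc, 3, 0, 1)
    tr <- selectChildTracks(extractTracks(ren$frames), "1")
    vel <- trackVelocities(tr)
    got <- vel$v_mps[vel$plane == cs$plane]
    truth <- ren$truth$obj1$velocity
    want <- truth$v_mps[truth$plane == cs$plane]
    expect_true(all(abs(abs(got) - abs(want)) / abs(want) < 0.15))
    expect_equal(sign(got), sign(want))
  }
})

test_that("Fourier velocities agree with the finite-difference oracle", {
  fx <- slabFixture()
  tr <- selectChildTracks(extractTracks(fx$frames), "1")
  vel <- trackVelocities(tr)
  for (sec in unique(vel$second)) {
    rows <- tr[match(((sec - 1) * 30 + 1):(sec * 30), tr$frame), ]
    fd <- oracleFiniteDiff(rows$cx_raw) # px/s = px per 30 frames
    got <- vel$v_axis_per_s[vel$plane == "x" & vel$second == sec]
    expect_lt(abs(got - fd), 1)
  }
})
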