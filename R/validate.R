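# Validation experiments: scripted-fixture studies the package runs on
# itself to quantify calibration and velocity recovery end to end.

#' Calibration recovery experiment
#'
#' Generates noiseless observations of a 1.75 m object exactly under the
#' canonical scaling line across a depth range, refits the calibration,
#' and reports the recovered coefficients with their relative errors.
#'
#' @param depths_mm depth grid in millimetres
#' @param trueHeight_m object height in metres
#' @return list with the fitted coefficients and relative errors
#' @export
calibrationRecoveryExperiment <- function(depths_mm = seq(1000, 4000, 100),
                                          trueHeight_m = 1.75) {
  gen <- canonicalCalibration()
  obs <- data.frame(
    depth_mm = depths_mm,
    px_height = trueHeight_m / scalingAt(gen, depths_mm))
  fit <- fitCalibration(obs, trueHeight_m = trueHeight_m)
  co <- calibrationCoef(fit)
  gco <- calibrationCoef(gen)
  list(slope = unname(co["slope"]), intercept = unname(co["intercept"]),
       rel_error_slope = unname(abs(co["slope"] - gco["slope"]) /
                                  gco["slope"]),
       rel_error_intercept = unname(abs(co["intercept"] - gco["intercept"]) /
                                      gco["intercept"]),
       n = nrow(obs))
}

#' Velocity recovery experiment
#'
#' Renders noiseless constant-velocity fixtures (back-and-forth 1-s legs)
#' for each requested plane/speed, runs the full segmentation, tracking
#' and Fourier-motion chain, and compares the per-second velocity
#' estimates against the scripted ground truth and against a
#' finite-difference oracle on the tracked centroid positions.
#'
#' For z-plane fixtures the script also drifts slowly in x so the
#' frame-differencing stage sees infrared change (depth change alone is
#' invisible to the infrared camera; a real moving child always moves in
#' the image plane too).
#'
#' @param speeds named list of numeric speed vectors (m/s) per plane,
#'   e.g. \code{list(x = c(0.5, 3.5), y = c(0.3, 2.5), z = c(0.5, 3.5))}
#' @param duration_s fixture length in seconds
#' @param depth_mm scripted depth for x/y fixtures
#' @param seed integer seed
#' @param config pipeline configuration
#' @param style fixture motion style, see
#'   \code{\link{makeConstantVelocityScript}}; \code{"alternating"}
#'   admits any speed, \code{"straight"} keeps windows reversal-free
#' @return data.frame with one row per fixture-second: plane, v_target,
#'   v_true_mps, v_est_mps, rel_error, oracle_axis_per_s, est_axis_per_s
#' @export
velocityRecoveryExperiment <- function(
    speeds = list(x = c(0.5, 2.0, 3.5), y = c(0.3, 1.4, 2.5),
                  z = c(0.5, 2.0, 3.5)),
    duration_s = 4, depth_mm = 3800, seed = 1L,
    config = defaultConfig(), style = "alternating") {
  cal <- canonicalCalibration()
  out <- NULL
  for (plane in names(speeds)) for (v in speeds[[plane]]) {
    if (plane == "z") {
      scz <- makeConstantVelocityScript(v, "z", duration_s = duration_s,
                                        style = style)
      scx <- makeConstantVelocityScript(0.4, "x", depth_mm = 2250,
                                        duration_s = duration_s,
                                        style = style)
      p <- scz@path; p$x_px <- scx@path$x_px
      sc <- trajectoryScript("obj1", shapeWidth = 24, shapeHeight = 120,
                             path = p, intensity = 30000)
    } else {
      sc <- makeConstantVelocityScript(v, plane, depth_mm = depth_mm,
                                       duration_s = duration_s,
                                       style = style)
    }
    ren <- renderSequence(sc, duration_s, noise_sd = 0, seed = seed,
                          calibration = cal)
    tracks <- extractTracks(ren$frames, config)
    lens <- vapply(trackData(tracks), nrow, integer(1L))
    child <- selectChildTracks(tracks, names(lens)[which.max(lens)])
    vel <- trackVelocities(child, cal, vMax = config$v_max, K = config$K,
                           useSmoothed = config$use_smoothed)
    truth <- ren$truth$obj1$velocity
    for (sec in unique(vel$second)) {
      est <- vel[vel$second == sec & vel$plane == plane, ]
      tru <- truth[truth$second == sec & truth$plane == plane, ]
      if (nrow(est) == 0L || nrow(tru) == 0L) next
      rows <- child[match(((sec - 1L) * config$K + 1L):(sec * config$K),
                          child$frame), ]
      qpos <- switch(plane, x = rows$cx_raw, y = rows$cy_raw,
                     z = as.numeric(rows$depth_mm))
      ok <- which(!is.na(qpos))
      oracle <- if (length(ok) >= 2L)
        (qpos[ok[length(ok)]] - qpos[ok[1L]]) /
          (ok[length(ok)] - ok[1L]) * config$K else NA_real_
      out <- rbind(out, data.frame(
        plane = plane, v_target = v, second = sec,
        v_true_mps = tru$v_mps, v_est_mps = est$v_mps,
        rel_error = abs(abs(est$v_mps) - abs(tru$v_mps)) /
          abs(tru$v_mps),
        oracle_axis_per_s = oracle,
        est_axis_per_s = est$v_axis_per_s))
    }
  }
  out
}
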