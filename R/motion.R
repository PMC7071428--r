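# Metric calibration, Fourier-transform velocity estimation per movement
# plane, and conversion of per-second velocities into accelerations and
# 5-s vector-magnitude epochs.
#
# Velocity estimation: within each 1-s window of K = 30 frames, the
# centroid's intensity is placed at its own coordinate in a zeroed 1-D
# projection array; multiplying that array elementwise by
# exp(i * 2*pi * a1 * q * dt) and summing collapses each frame to one
# complex sample s_k = I_k * exp(i * 2*pi * a1 * q_k * dt). For an object
# moving at a constant v (axis units/frame) the samples form a complex
# tone whose frequency is proportional to v. With a1 = K / v_max, where
# v_max is the maximum expected velocity in axis units per frame, the
# expected velocity range spans the K spectral bins exactly once, so the
# first peak of the FFT magnitude spectrum locates the velocity. The
# peak is refined below bin resolution via the phase of the lag-1
# autocovariance of the samples (standard single-tone frequency
# refinement), and the direction ambiguity inherent to a complex tone
# (a phase increment of theta is indistinguishable from theta - 2*pi)
# is resolved from the net drift of the projected coordinate.

#' Canonical depth-to-scale calibration
#'
#' The linear scaling used by the synthetic renderer as the true camera
#' geometry: scale(depth) = 1.5e-6 * depth_mm + 6.4e-4 m/pixel.
#'
#' @return a \linkS4class{CalibrationModel}
#' @export
canonicalCalibration <- function() {
  new("CalibrationModel", slope = 1.5e-6, intercept = 6.4e-4, nObs = 0L)
}

#' Fit the depth-to-scale calibration
#'
#' An object of known physical height is observed at several depths; each
#' observation yields a scale value true_height / pixel_height (m/pixel).
#' Ordinary least squares of scale on depth gives the calibration line.
#'
#' @param observations data.frame with columns depth_mm, px_height
#' @param trueHeight_m physical height of the calibration object (m)
#' @return a \linkS4class{CalibrationModel}
#' @export
fitCalibration <- function(observations, trueHeight_m = 1.75) {
  obs <- as.data.frame(observations)
  stopifnot(all(c("depth_mm", "px_height") %in% names(obs)))
  if (any(obs$px_height <= 0)) stop("pixel heights must be positive")
  if (length(unique(obs$depth_mm)) < 2L)
    stop("calibration requires at least two distinct depths")
  scale <- trueHeight_m / obs$px_height
  fit <- stats::lm(scale ~ depth_mm, data = data.frame(
    scale = scale, depth_mm = obs$depth_mm))
  new("CalibrationModel", slope = unname(stats::coef(fit)[2L]),
      intercept = unname(stats::coef(fit)[1L]), nObs = nrow(obs))
}

#' Fourier velocity estimate over one 1-s window
#'
#' @param positions numeric vector of per-frame projected coordinates
#'   (pixels for x/y, mm for z); \code{NA} marks unevaluable frames
#' @param intensities per-frame weights (centroid intensities); recycled
#' @param vMaxAxisPerFrame maximum expected velocity in axis units per
#'   frame (defines the spectral scaling a1 = K / vMax)
#' @param dt inter-frame interval in seconds
#' @param K frames per window
#' @return signed velocity in axis units per second, or \code{NA} when
#'   more than half of the window is unevaluable
#' @export
fourierVelocity <- function(positions, intensities = 1,
                            vMaxAxisPerFrame, dt = 1 / 30, K = 30L) {
  q <- as.numeric(positions)
  w <- rep_len(as.numeric(intensities), length(q))
  ok <- !is.na(q) & !is.na(w)
  if (sum(ok) < ceiling(length(q) / 2) || sum(ok) < 2L) return(NA_real_)
  a1 <- K / vMaxAxisPerFrame
  alpha <- 2 * pi * a1 * dt          # phase per axis unit
  s <- complex(modulus = w, argument = alpha * q)
  s[!ok] <- NA
  # FFT magnitude spectrum over the available samples (first peak = coarse
  # velocity); refinement below uses the autocovariance phase
  sv <- s[ok]
  spec <- Mod(stats::fft(sv))
  m0 <- which.max(spec) - 1L
  # per-pair phase increments over consecutive valid frames
  idx <- which(ok[-length(ok)] & ok[-1L])
  if (length(idx) == 0L) return(NA_real_)
  phi <- Arg(s[idx + 1L] * Conj(s[idx]))
  # choose each increment's 2*pi branch from the net coordinate drift
  # (a complex tone's phase is only known modulo a full turn)
  iok <- which(ok)
  drift <- (q[iok[length(iok)]] - q[iok[1L]]) /
    (iok[length(iok)] - iok[1L])      # axis units / frame
  thetaPred <- alpha * drift
  phi <- phi + 2 * pi * round((thetaPred - phi) / (2 * pi))
  vFrame <- mean(phi) / alpha         # axis units per frame
  structure(vFrame / dt, peak_bin = m0)   # axis units per second
}

#' Convert an axis velocity to metres per second
#'
#' x/y velocities (pixels/s) are scaled by the calibration evaluated at
#' the observed depth; z velocities are already metric (mm/s). Values
#' beyond the plane's expected maximum are clipped with a warning.
#'
#' @param v_axis velocity in axis units per second (px/s or mm/s)
#' @param depth_mm depth reading used for the scaling (x/y planes)
#' @param calibration a \linkS4class{CalibrationModel}
#' @param plane \code{"x"}, \code{"y"} or \code{"z"}
#' @param vMax named vector of maximum expected speeds (m/s) per plane
#' @return velocity in m/s (signed), or \code{NA} when depth is missing
#' @export
toMps <- function(v_axis, depth_mm, calibration, plane = c("x", "y", "z"),
                  vMax = c(x = 4, y = 2.8, z = 4)) {
  plane <- match.arg(plane)
  if (is.na(v_axis)) return(NA_real_)
  if (plane == "z") {
    v <- v_axis / 1000
  } else {
    if (is.na(depth_mm)) return(NA_real_)
    v <- v_axis * scalingAt(calibration, depth_mm)
  }
  lim <- unname(vMax[plane])
  if (is.finite(v) && abs(v) > lim) {
    warning(sprintf("velocity %.2f m/s clipped at +/-%.1f (plane %s)",
                    v, lim, plane))
    v <- sign(v) * lim
  }
  v
}

#' Per-second per-plane velocities of one track
#'
#' Splits a track into consecutive 1-s windows of \code{K} frames
#' (aligned with the frame sequence), estimates the Fourier velocity in
#' each plane, and converts to m/s. Windows with more than half of the
#' frames unobserved yield missing samples.
#'
#' @param track data.frame of track entries (from
#'   \code{\link{selectChildTracks}} or \code{trackData})
#' @param calibration a \linkS4class{CalibrationModel}
#' @param vMax named maximum expected speeds (m/s) per plane
#' @param K frames per window
#' @param useSmoothed use Kalman-smoothed centroids instead of raw
#' @return data.frame with columns second, plane, v_axis_per_s, v_mps,
#'   depth_mm, n_valid
#' @export
trackVelocities <- function(track, calibration = canonicalCalibration(),
                            vMax = c(x = 4, y = 2.8, z = 4), K = 30L,
                            useSmoothed = FALSE) {
  if (nrow(track) == 0L) return(data.frame())
  lastFrame <- max(track$frame)
  nSec <- floor(lastFrame / K)
  out <- NULL
  for (sec in seq_len(nSec)) {
    frames <- ((sec - 1L) * K + 1L):(sec * K)
    rows <- track[match(frames, track$frame), , drop = FALSE]
    ts <- rows$timestamp_ms[!is.na(rows$timestamp_ms)]
    # timestamps are stored as integer ms; average over the window span so
    # rounding does not bias the frame interval
    dt <- if (length(ts) > 1L)
      (ts[length(ts)] - ts[1L]) / (length(ts) - 1L) / 1000 else 1 / K
    depth <- stats::median(rows$depth_mm, na.rm = TRUE)
    scl <- scalingAt(calibration, depth)
    xs <- if (useSmoothed) rows$cx else rows$cx_raw
    ys <- if (useSmoothed) rows$cy else rows$cy_raw
    nValid <- sum(!is.na(xs))
    for (plane in c("x", "y", "z")) {
      qv <- switch(plane, x = xs, y = ys, z = as.numeric(rows$depth_mm))
      vMaxAxis <- switch(plane,
        x = , y = unname(vMax[plane]) / scl / K,   # px per frame
        z = unname(vMax["z"]) * 1000 / K)          # mm per frame
      vAxis <- if (is.na(depth) && plane != "z" ||
                   all(is.na(qv))) NA_real_ else
        fourierVelocity(qv, rows$ir, vMaxAxisPerFrame = vMaxAxis,
                        dt = dt, K = K)
      vm <- toMps(vAxis, depth, calibration, plane, vMax)
      out <- rbind(out, data.frame(
        second = sec, plane = plane, v_axis_per_s = vAxis, v_mps = vm,
        depth_mm = depth, n_valid = nValid))
    }
  }
  out
}

#' Per-second accelerations from a velocity series
#'
#' First differences of the per-second velocities divided by the sampling
#' interval and by standard gravity, yielding accelerations in g. The
#' first sample is 0; gaps in the velocity series propagate as missing.
#'
#' @param v numeric vector of per-second velocities (m/s)
#' @param dt sampling interval in seconds
#' @return numeric vector of accelerations in g
#' @export
accelerations <- function(v, dt = 1) {
  n <- length(v)
  if (n == 0L) return(numeric(0))
  a <- c(0, diff(v) / dt / standardGravity)
  a[c(FALSE, is.na(v[-n]))] <- NA_real_
  a[is.na(v)] <- NA_real_
  a[1L] <- if (is.na(v[1L])) NA_real_ else 0
  a
}

#' Vector-magnitude 5-s epochs from triaxial accelerations
#'
#' Per second, VM = sqrt(ax^2 + ay^2 + az^2) * 1000; epochs aggregate
#' consecutive non-overlapping bins of \code{epochS} seconds with the
#' chosen statistic. Epochs with 3 or more missing seconds are missing.
#'
#' @param ax,ay,az per-second accelerations in g (equal length)
#' @param epochS epoch length in seconds
#' @param statistic \code{"mean"} or \code{"sum"} over available seconds
#' @return data.frame with columns epoch_index, epoch_start_s, vm_value,
#'   n_valid_seconds
#' @export
vmEpochs <- function(ax, ay, az, epochS = 5L, statistic = c("mean", "sum")) {
  statistic <- match.arg(statistic)
  stopifnot(length(ax) == length(ay), length(ay) == length(az))
  vmSec <- sqrt(ax^2 + ay^2 + az^2) * 1000
  nEpoch <- floor(length(vmSec) / epochS)
  out <- NULL
  for (e in seq_len(nEpoch)) {
    sel <- ((e - 1L) * epochS + 1L):(e * epochS)
    vals <- vmSec[sel]
    nMissing <- sum(is.na(vals))
    vm <- if (nMissing >= 3L) NA_real_ else
      if (statistic == "mean") mean(vals, na.rm = TRUE) else
        sum(vals, na.rm = TRUE)
    out <- rbind(out, data.frame(
      epoch_index = e, epoch_start_s = (e - 1L) * epochS,
      vm_value = vm, n_valid_seconds = epochS - nMissing))
  }
  out
}

#' Vector-magnitude epochs straight from a child track
#'
#' Convenience wrapper chaining \code{\link{trackVelocities}},
#' \code{\link{accelerations}} and \code{\link{vmEpochs}}.
#'
#' @param track child track data.frame
#' @param calibration a \linkS4class{CalibrationModel}
#' @param config pipeline configuration
#' @return data.frame of VM epochs
#' @export
epochsFromTrack <- function(track, calibration = canonicalCalibration(),
                            config = defaultConfig()) {
  vel <- trackVelocities(track, calibration,
                         vMax = config$v_max, K = config$K,
                         useSmoothed = config$use_smoothed)
  if (nrow(vel) == 0L) return(data.frame())
  acc <- lapply(c("x", "y", "z"), function(p)
    accelerations(vel$v_mps[vel$plane == p]))
  vmEpochs(acc[[1L]], acc[[2L]], acc[[3L]], epochS = config$epoch_s,
           statistic = config$epoch_statistic)
}
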