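# Synthetic stand-in for the 3D camera: renders infrared/depth frame
# sequences from scripted object trajectories with exact ground truth.

FRAME_W <- 640L
FRAME_H <- 480L
FPS <- 30L

# Study-condition defaults for the rendered scene: a uniform mid-gray
# infrared background so the difference threshold has realistic sensor
# noise to reject, and a constant far wall on the depth stream (the play
# area is a closed room).
BG_IR <- 8000L
BG_DEPTH <- 4000L

#' Create a trajectory script
#'
#' @param objectId label for the object
#' @param shape \code{"rectangle"} or \code{"ellipse"}
#' @param shapeWidth,shapeHeight object size in pixels
#' @param path data.frame with columns t_ms, x_px, y_px, depth_mm giving
#'   waypoints of the shape centre; positions between waypoints are
#'   linearly interpolated
#' @param intensity infrared pixel value of the object (uint16)
#' @param dropoutSpans data.frame with columns start_ms, end_ms during
#'   which the depth sensor cannot quantise the object (depth reads 0)
#' @return a \linkS4class{TrajectoryScript}
#' @export
trajectoryScript <- function(objectId, shape = "rectangle",
                             shapeWidth = 40, shapeHeight = 40,
                             path, intensity = 30000,
                             dropoutSpans = data.frame(start_ms = numeric(0),
                                                       end_ms = numeric(0))) {
  new("TrajectoryScript", objectId = as.character(objectId), shape = shape,
      shapeWidth = shapeWidth, shapeHeight = shapeHeight,
      path = as.data.frame(path), intensity = intensity,
      dropoutSpans = as.data.frame(dropoutSpans))
}

# Interpolate the scripted path at arbitrary times (ms). Constant
# extrapolation beyond the last waypoint.
interpolatePath <- function(script, t_ms) {
  p <- script@path
  if (nrow(p) == 1L) {
    return(data.frame(t_ms = t_ms, x_px = p$x_px, y_px = p$y_px,
                      depth_mm = p$depth_mm))
  }
  data.frame(
    t_ms = t_ms,
    x_px = stats::approx(p$t_ms, p$x_px, t_ms, rule = 2)$y,
    y_px = stats::approx(p$t_ms, p$y_px, t_ms, rule = 2)$y,
    depth_mm = stats::approx(p$t_ms, p$depth_mm, t_ms, rule = 2)$y)
}

# Rasterise one object at a continuous centre position; returns 1-based
# index ranges / logical mask. Positions are 0-based pixel centres.
rasterizeShape <- function(script, x, y, t_ms) {
  w <- round(script@shapeWidth); h <- round(script@shapeHeight)
  x0 <- round(x - (w - 1) / 2); y0 <- round(y - (h - 1) / 2)
  if (x0 < 0 || x0 + w > FRAME_W || y0 < 0 || y0 + h > FRAME_H)
    stop(sprintf("object '%s' leaves the frame bounds at t = %.0f ms",
                 script@objectId, t_ms))
  ix <- (x0 + 1L):(x0 + w)          # 1-based matrix indices
  iy <- (y0 + 1L):(y0 + h)
  if (script@shape == "rectangle") {
    list(ix = ix, iy = iy, mask = matrix(TRUE, w, h))
  } else {
    cx <- x0 + (w - 1) / 2; cy <- y0 + (h - 1) / 2   # 0-based centre
    mx <- outer(((ix - 1) - cx) / (w / 2), rep(1, h))
    my <- outer(rep(1, w), ((iy - 1) - cy) / (h / 2))
    list(ix = ix, iy = iy, mask = mx^2 + my^2 <= 1)
  }
}

inDropout <- function(script, t_ms) {
  d <- script@dropoutSpans
  nrow(d) > 0L && any(t_ms >= d$start_ms & t_ms <= d$end_ms)
}

# Map a scripted speed (m/s) to a CARS activity code. Thresholds emulate
# the observable behaviours: near-still -> lying/sitting, slow sway ->
# standing, gait speeds -> walking, above typical walking -> running.
carsCodeFromSpeed <- function(speed_mps) {
  ifelse(speed_mps < 0.05, 1L,
         ifelse(speed_mps < 0.5, 2L,
                ifelse(speed_mps < 1.5, 3L, 4L)))
}

#' Render an infrared/depth frame sequence from trajectory scripts
#'
#' Produces \code{floor(duration_s * 30)} frame pairs at 640 x 480 px and a
#' nominal 30 Hz. Infrared frames contain the scripted shapes over a
#' uniform mid-gray background with optional Gaussian sensor noise; depth
#' frames hold each object's scripted depth (mm) inside its shape, 0
#' during its dropout spans, and a constant far-plane value elsewhere.
#'
#' @param scripts a \linkS4class{TrajectoryScript} or list of them
#' @param duration_s sequence duration in seconds (> 0)
#' @param noise_sd standard deviation of the additive infrared noise
#' @param seed integer seed; the same seed reproduces the sequence
#'   bit-identically
#' @param calibration \linkS4class{CalibrationModel} used to express the
#'   scripted ground-truth velocities in m/s
#' @return a list with elements \code{frames} (a
#'   \linkS4class{FrameSequence}) and \code{truth} (a list with per-frame
#'   true centroids, per-second per-plane velocities, and per-second CARS
#'   codes)
#' @export
renderSequence <- function(scripts, duration_s, noise_sd = 0, seed = 1L,
                           calibration = canonicalCalibration()) {
  stopifnot(duration_s > 0, noise_sd >= 0)
  if (is(scripts, "TrajectoryScript")) scripts <- list(scripts)
  set.seed(seed)
  nF <- as.integer(floor(duration_s * FPS))
  tExact <- (seq_len(nF) - 1L) * (1000 / FPS)
  tms <- round(tExact)      # stored clock is integer milliseconds
  pos <- lapply(scripts, interpolatePath, t_ms = tExact)

  ir <- vector("list", nF); dp <- vector("list", nF)
  for (k in seq_len(nF)) {
    if (noise_sd > 0) {
      fr <- matrix(as.integer(clipUint16(round(
        BG_IR + stats::rnorm(FRAME_W * FRAME_H, 0, noise_sd)))),
        FRAME_W, FRAME_H)
    } else {
      fr <- matrix(BG_IR, FRAME_W, FRAME_H)
    }
    dfr <- matrix(BG_DEPTH, FRAME_W, FRAME_H)
    for (s in seq_along(scripts)) {
      sc <- scripts[[s]]
      r <- rasterizeShape(sc, pos[[s]]$x_px[k], pos[[s]]$y_px[k], tExact[k])
      sub <- fr[r$ix, r$iy]; sub[r$mask] <- as.integer(sc@intensity)
      fr[r$ix, r$iy] <- sub
      dsub <- dfr[r$ix, r$iy]
      dval <- if (inDropout(sc, tExact[k])) 0L else
        as.integer(round(pos[[s]]$depth_mm[k]))
      dsub[r$mask] <- dval
      dfr[r$ix, r$iy] <- dsub
    }
    ir[[k]] <- fr; dp[[k]] <- dfr
  }
  frames <- new("FrameSequence", infrared = ir, depth = dp,
                timestamps = tms, width = FRAME_W, height = FRAME_H)

  truth <- groundTruthFromScripts(scripts, pos, tms, duration_s, calibration)
  list(frames = frames, truth = truth)
}

# Exact ground truth from the scripts: per-frame centroids, per-second
# finite-difference velocities in each plane (axis units/s and m/s), and
# per-second CARS codes from the overall speed.
groundTruthFromScripts <- function(scripts, pos, tms, duration_s,
                                   calibration) {
  nSec <- floor(duration_s)
  out <- list()
  for (s in seq_along(scripts)) {
    sc <- scripts[[s]]
    cent <- data.frame(frame = seq_along(tms), timestamp_ms = tms,
                       x_px = pos[[s]]$x_px, y_px = pos[[s]]$y_px,
                       depth_mm = pos[[s]]$depth_mm)
    vel <- NULL
    for (sec in seq_len(nSec)) {
      p0 <- interpolatePath(sc, (sec - 1) * 1000)
      p1 <- interpolatePath(sc, sec * 1000)
      dmid <- interpolatePath(sc, (sec - 0.5) * 1000)$depth_mm
      scl <- scalingAt(calibration, dmid)
      vax <- c(x = p1$x_px - p0$x_px, y = p1$y_px - p0$y_px,
               z = p1$depth_mm - p0$depth_mm)
      vmps <- c(x = unname(vax["x"]) * scl, y = unname(vax["y"]) * scl,
                z = unname(vax["z"]) / 1000)
      vel <- rbind(vel, data.frame(
        second = sec, plane = c("x", "y", "z"),
        v_axis_per_s = unname(vax), v_mps = unname(vmps),
        depth_mm = dmid))
    }
    speed <- sqrt(tapply(vel$v_mps^2, vel$second, sum))
    cars <- data.frame(second = seq_len(nSec),
                       code = carsCodeFromSpeed(as.numeric(speed)))
    out[[sc@objectId]] <- list(centroids = cent, velocity = vel,
                               cars = cars)
  }
  out
}

#' Constant-velocity script for validation fixtures
#'
#' Builds a script whose centre moves at a constant speed along one
#' plane. With \code{style = "alternating"} the motion reverses direction
#' every second (each 1-s leg a constant-velocity segment aligned with
#' the analysis windows) so arbitrary speeds stay inside the frame; with
#' \code{style = "straight"} the motion is one uninterrupted leg, which
#' restricts the feasible speed but keeps every analysis window free of
#' direction reversals. For x/y scripts the pixel speed is derived from
#' the requested metric speed via the calibration at the (constant)
#' scripted depth.
#'
#' @param v_mps target speed in m/s
#' @param plane \code{"x"}, \code{"y"} or \code{"z"}
#' @param depth_mm scripted depth (constant for x/y; mid-range for z)
#' @param duration_s total scripted duration in seconds
#' @param shapeWidth,shapeHeight object size in pixels
#' @param calibration \linkS4class{CalibrationModel} giving m/pixel
#' @param objectId label
#' @param style \code{"alternating"} or \code{"straight"}
#' @return a \linkS4class{TrajectoryScript}
#' @export
makeConstantVelocityScript <- function(v_mps, plane = c("x", "y", "z"),
                                       depth_mm = 3800, duration_s = 6,
                                       shapeWidth = NULL, shapeHeight = NULL,
                                       calibration = canonicalCalibration(),
                                       objectId = "obj1",
                                       style = c("alternating",
                                                 "straight")) {
  plane <- match.arg(plane)
  style <- match.arg(style)
  # narrow slab perpendicular to the motion so the frame-difference region
  # stays a single connected component at low speeds
  if (is.null(shapeWidth))
    shapeWidth <- if (plane == "y") 120 else 24
  if (is.null(shapeHeight))
    shapeHeight <- if (plane == "y") 24 else 120
  nSec <- ceiling(duration_s)
  scl <- scalingAt(calibration, depth_mm)
  tt <- (0:nSec) * 1000
  leg <- if (style == "alternating") rep(c(1, -1), length.out = nSec)
         else rep(1, nSec)
  if (plane == "z") {
    span <- v_mps * 1000                    # mm per second-long leg
    d0 <- max(450, 2250 - span / 2)
    dpath <- d0 + c(0, cumsum(leg * span))
    path <- data.frame(t_ms = tt, x_px = 320, y_px = 240, depth_mm = dpath)
  } else {
    span <- v_mps / scl                     # px per second-long leg
    extent <- if (style == "alternating") span else span * nSec
    half <- if (plane == "x") FRAME_W else FRAME_H
    margin <- (if (plane == "x") shapeWidth else shapeHeight) / 2 + 2
    if (extent > half - 2 * margin)
      stop("requested speed does not fit in the frame at this depth")
    lo <- (half - 1) / 2 - extent / 2
    lo <- max(margin, min(lo, half - margin - extent))
    coord <- lo + c(0, cumsum(leg * span))
    if (plane == "x")
      path <- data.frame(t_ms = tt, x_px = coord, y_px = 240,
                         depth_mm = depth_mm)
    else
      path <- data.frame(t_ms = tt, x_px = 320, y_px = coord,
                         depth_mm = depth_mm)
  }
  trajectoryScript(objectId, shape = "rectangle",
                   shapeWidth = shapeWidth, shapeHeight = shapeHeight,
                   path = path, intensity = 30000)
}

#' Write rendered ground truth to disk
#'
#' Velocities and CARS codes go to CSV, centroids to JSON, matching the
#' outputs the rest of the pipeline consumes.
#'
#' @param truth ground-truth list as returned by \code{renderSequence}
#' @param dir output directory (created if needed)
#' @export
writeGroundTruth <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  vel <- do.call(rbind, lapply(names(truth), function(id)
    cbind(object_id = id, truth[[id]]$velocity)))
  cars <- do.call(rbind, lapply(names(truth), function(id)
    cbind(object_id = id, truth[[id]]$cars)))
  utils::write.csv(vel, file.path(dir, "truth_velocity.csv"),
                   row.names = FALSE)
  utils::write.csv(cars, file.path(dir, "truth_cars.csv"),
                   row.names = FALSE)
  cent <- lapply(truth, function(x) x$centroids)
  jsonlite::write_json(cent, file.path(dir, "truth_centroids.json"),
                       dataframe = "columns", digits = NA)
  invisible(dir)
}
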