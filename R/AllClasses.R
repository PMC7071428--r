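#' @import methods
NULL

#' Paired infrared/depth frame sequence
#'
#' Container for a sequence of simultaneously acquired 16-bit infrared and
#' depth frames. Infrared pixel values are raw sensor intensities; depth
#' pixel values are sensor-to-object distances in millimetres, with 0
#' meaning no reading. Frames are stored as \code{width x height} integer
#' matrices (x along rows, y along columns); user-facing pixel coordinates
#' are 0-based with pixel centres at integer positions.
#'
#' @slot infrared list of integer matrices (one per frame)
#' @slot depth list of integer matrices (one per frame)
#' @slot timestamps numeric vector of acquisition times in milliseconds
#' @slot width,height frame dimensions in pixels
#' @export
setClass("FrameSequence",
  representation(infrared = "list", depth = "list", timestamps = "numeric",
                 width = "integer", height = "integer"),
  validity = function(object) {
    n <- length(object@infrared)
    if (length(object@depth) != n)
      return("infrared and depth streams differ in length")
    if (length(object@timestamps) != n)
      return("one timestamp per frame required")
    if (n > 0L && is.unsorted(object@timestamps))
      return("timestamps must be monotone non-decreasing")
    for (i in seq_len(n)) {
      if (!identical(dim(object@infrared[[i]]),
                     c(object@width, object@height)) ||
          !identical(dim(object@depth[[i]]),
                     c(object@width, object@height)))
        return(sprintf("frame %d has wrong dimensions", i))
    }
    TRUE
  })

#' Scripted object trajectory for the synthetic frame generator
#'
#' Describes one rendered object: its shape and size in pixels, its path as
#' waypoints (time in ms, x/y pixel position of the shape centre, depth in
#' mm), its infrared intensity, and time spans during which the depth
#' sensor drops out (depth reads 0 inside the object).
#'
#' @slot objectId character label
#' @slot shape \code{"rectangle"} or \code{"ellipse"}
#' @slot shapeWidth,shapeHeight size in pixels
#' @slot path data.frame with columns t_ms, x_px, y_px, depth_mm
#' @slot intensity infrared pixel value (<= 65535)
#' @slot dropoutSpans data.frame with columns start_ms, end_ms
#' @export
setClass("TrajectoryScript",
  representation(objectId = "character", shape = "character",
                 shapeWidth = "numeric", shapeHeight = "numeric",
                 path = "data.frame", intensity = "numeric",
                 dropoutSpans = "data.frame"),
  validity = function(object) {
    p <- object@path
    need <- c("t_ms", "x_px", "y_px", "depth_mm")
    if (!all(need %in% names(p)))
      return("path needs columns t_ms, x_px, y_px, depth_mm")
    if (nrow(p) >= 2L && any(diff(p$t_ms) <= 0))
      return("path timestamps must be strictly increasing")
    if (any(p$x_px < 0 | p$x_px >= 640) || any(p$y_px < 0 | p$y_px >= 480))
      return("path positions must satisfy 0 <= x < 640, 0 <= y < 480")
    if (any(p$depth_mm < 0)) return("depth_mm must be >= 0")
    if (object@intensity < 0 || object@intensity > 65535)
      return("intensity must fit in uint16")
    if (!object@shape %in% c("rectangle", "ellipse"))
      return("shape must be 'rectangle' or 'ellipse'")
    TRUE
  })

#' Binary difference mask between two infrared frames
#'
#' @slot mask binary integer matrix
#' @slot foregroundCount number of 1-pixels
#' @slot evaluable FALSE when the foreground count exceeds the frame noise
#'   threshold (the frame is too noisy to segment)
#' @export
setClass("DifferenceMask",
  representation(mask = "matrix", foregroundCount = "integer",
                 evaluable = "logical"),
  validity = function(object) {
    if (object@foregroundCount != sum(object@mask > 0))
      return("foregroundCount must equal the number of 1-pixels")
    TRUE
  })

#' Set of object tracks extracted from a frame sequence
#'
#' Each track is a data.frame with one row per frame in which the object
#' was observed: timestamp_ms, frame, raw centroid (cx_raw, cy_raw),
#' Kalman-smoothed centroid (cx, cy), bounding box (bx, by, bw, bh),
#' infrared intensity at the centroid (ir) and depth in mm (depth_mm,
#' NA when the windowed depth search failed).
#'
#' @slot tracks named list of per-track data.frames (names = track ids)
#' @slot firstSeen numeric vector of first-detection timestamps (ms)
#' @export
setClass("TrackSet",
  representation(tracks = "list", firstSeen = "numeric"),
  validity = function(object) {
    if (length(object@firstSeen) != length(object@tracks))
      return("one firstSeen timestamp per track required")
    for (tr in object@tracks)
      if (nrow(tr) > 1L && is.unsorted(tr$timestamp_ms))
        return("track entries must be time-ordered")
    TRUE
  })

#' Depth-to-scale calibration model
#'
#' Linear model mapping a depth reading (mm) to the metre-per-pixel scale
#' of the image at that depth: scale(depth) = slope * depth + intercept.
#'
#' @slot slope m/pixel per mm of depth
#' @slot intercept m/pixel at zero depth
#' @slot nObs number of calibration observations used in the fit
#' @export
setClass("CalibrationModel",
  representation(slope = "numeric", intercept = "numeric", nObs = "integer"),
  validity = function(object) {
    if (length(object@slope) != 1L || length(object@intercept) != 1L)
      return("slope and intercept must be scalars")
    TRUE
  })

#' Single-feature decision-tree intensity classifier
#'
#' Holds either three one-vs-all CART fits (SED, LPA, MVPA each against the
#' other two combined) or one multiclass CART fit, trained on the vector
#' magnitude as the sole feature.
#'
#' @slot mode \code{"onevsall"} or \code{"multiclass"}
#' @slot fits named list of rpart fits
#' @slot classes intensity class labels
#' @slot params training hyperparameters
#' @export
setClass("IntensityModel",
  representation(mode = "character", fits = "list", classes = "character",
                 params = "list"),
  validity = function(object) {
    if (!object@mode %in% c("onevsall", "multiclass"))
      return("mode must be 'onevsall' or 'multiclass'")
    TRUE
  })

#' Classifier evaluation report
#'
#' @slot perClass data.frame with columns class, auc, ci_low, ci_high,
#'   sensitivity, specificity, n_pos, n_neg
#' @slot confusion confusion matrix (rows = observed, cols = predicted);
#'   only populated for multiclass models
#' @slot params evaluation settings (n_boot, seed)
#' @export
setClass("EvaluationReport",
  representation(perClass = "data.frame", confusion = "matrix",
                 params = "list"))

setMethod("show", "FrameSequence", function(object) {
  cat(sprintf("FrameSequence: %d frame pair(s), %dx%d px\n",
              length(object@infrared), object@width, object@height))
  if (length(object@timestamps) > 1L)
    cat(sprintf("  span %.2f s (median dt %.1f ms)\n",
                diff(range(object@timestamps)) / 1000,
                stats::median(diff(object@timestamps))))
})

setMethod("show", "TrackSet", function(object) {
  cat(sprintf("TrackSet: %d track(s)\n", length(object@tracks)))
  for (id in names(object@tracks))
    cat(sprintf("  track %s: %d frame(s), first seen %.0f ms\n",
                id, nrow(object@tracks[[id]]),
                object@firstSeen[[match(id, names(object@tracks))]]))
})

setMethod("show", "CalibrationModel", function(object) {
  cat(sprintf(
    "CalibrationModel: m/pixel = %.4g * depth_mm + %.4g  (n = %d)\n",
    object@slope, object@intercept, object@nObs))
})

setMethod("show", "IntensityModel", function(object) {
  cat(sprintf("IntensityModel (%s) on classes: %s\n", object@mode,
              paste(object@classes, collapse = ", ")))
})

setMethod("show", "EvaluationReport", function(object) {
  cat("EvaluationReport\n")
  print(object@perClass, row.names = FALSE, digits = 3)
})

#' Number of frames in a sequence
#' @param object a FrameSequence
#' @export
setGeneric("nFrames", function(object) standardGeneric("nFrames"))

#' @rdname nFrames
#' @export
setMethod("nFrames", "FrameSequence",
          function(object) length(object@infrared))

#' Frame timestamps in milliseconds
#' @param object a FrameSequence or TrackSet
#' @export
setGeneric("frameTimes", function(object) standardGeneric("frameTimes"))

#' @rdname frameTimes
#' @export
setMethod("frameTimes", "FrameSequence", function(object) object@timestamps)

#' Access a single infrared or depth frame
#' @param object a FrameSequence
#' @param i frame index (1-based)
#' @export
setGeneric("irFrame", function(object, i) standardGeneric("irFrame"))

#' @rdname irFrame
#' @export
setMethod("irFrame", "FrameSequence", function(object, i)
  object@infrared[[i]])

#' @rdname irFrame
#' @export
setGeneric("depthFrame", function(object, i) standardGeneric("depthFrame"))

#' @rdname irFrame
#' @export
setMethod("depthFrame", "FrameSequence", function(object, i)
  object@depth[[i]])

#' Track identifiers of a TrackSet
#' @param object a TrackSet
#' @export
setGeneric("trackIds", function(object) standardGeneric("trackIds"))

#' @rdname trackIds
#' @export
setMethod("trackIds", "TrackSet", function(object) names(object@tracks))

#' Per-track data of a TrackSet
#' @param object a TrackSet
#' @export
setGeneric("trackData", function(object) standardGeneric("trackData"))

#' @rdname trackData
#' @export
setMethod("trackData", "TrackSet", function(object) object@tracks)

#' Metre-per-pixel scale at a given depth
#'
#' Evaluates the linear calibration at the supplied depth reading(s).
#'
#' @param object a CalibrationModel
#' @param depth_mm depth value(s) in millimetres
#' @return metre-per-pixel scale value(s)
#' @export
setGeneric("scalingAt", function(object, depth_mm)
  standardGeneric("scalingAt"))

#' @rdname scalingAt
#' @export
setMethod("scalingAt", "CalibrationModel", function(object, depth_mm)
  object@slope * depth_mm + object@intercept)

#' Calibration coefficients
#' @param object a CalibrationModel
#' @return named numeric vector with slope and intercept
#' @export
setGeneric("calibrationCoef", function(object)
  standardGeneric("calibrationCoef"))

#' @rdname calibrationCoef
#' @export
setMethod("calibrationCoef", "CalibrationModel", function(object)
  c(slope = object@slope, intercept = object@intercept))

#' Per-class evaluation metrics
#' @param object an EvaluationReport
#' @export
setGeneric("classMetrics", function(object) standardGeneric("classMetrics"))

#' @rdname classMetrics
#' @export
setMethod("classMetrics", "EvaluationReport", function(object)
  object@perClass)

#' Confusion matrix of a multiclass evaluation
#' @param object an EvaluationReport
#' @export
setGeneric("confusionMatrix", function(object)
  standardGeneric("confusionMatrix"))

#' @rdname confusionMatrix
#' @export
setMethod("confusionMatrix", "EvaluationReport", function(object)
  object@confusion)
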