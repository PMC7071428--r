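# Frame-differencing segmentation with the morphological clean-up chain:
# difference mask -> Sobel edge enhancement -> 3x3 majority fill ->
# closing (disk r = 9) -> reconstruction against the difference mask ->
# geodesic dilation (25 px square) -> 8-connected hole fill -> one
# thinning pass -> component-size filtering.

#' Binary difference mask between consecutive infrared frames
#'
#' A pixel is foreground when the absolute intensity difference between
#' the two frames exceeds \code{pixelThreshold}. Frames whose total
#' foreground count exceeds \code{frameThreshold} are flagged unevaluable
#' (too noisy to segment) and are skipped downstream.
#'
#' @param frame_i,frame_j integer matrices of equal dimensions
#' @param pixelThreshold per-pixel absolute-difference threshold (> 0)
#' @param frameThreshold maximum foreground count for an evaluable frame
#' @return a \linkS4class{DifferenceMask}
#' @export
differenceMask <- function(frame_i, frame_j, pixelThreshold = 1400L,
                           frameThreshold = 14000L) {
  if (!identical(dim(frame_i), dim(frame_j)))
    stop("frames differ in shape")
  stopifnot(pixelThreshold > 0)
  d <- (abs(frame_i - frame_j) > pixelThreshold) + 0L
  fg <- sum(d)
  new("DifferenceMask", mask = d, foregroundCount = as.integer(fg),
      evaluable = fg <= frameThreshold)
}

#' Sobel edge enhancement of a binary mask
#'
#' Applies the 3x3 Sobel operator in both directions and binarises the
#' gradient magnitude at > 0. Borders are replicate-padded so a constant
#' image has no gradient anywhere (the frame boundary is not an edge).
#'
#' @param mask a \linkS4class{DifferenceMask} or binary matrix
#' @return binary integer matrix
#' @export
edgeEnhance <- function(mask) {
  m <- if (is(mask, "DifferenceMask")) mask@mask else (mask > 0) + 0L
  nr <- nrow(m); nc <- ncol(m)
  pad <- matrix(0L, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- m
  pad[1L, ] <- pad[2L, ]; pad[nr + 2L, ] <- pad[nr + 1L, ]
  pad[, 1L] <- pad[, 2L]; pad[, nc + 2L] <- pad[, nc + 1L]
  sx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3)   # gradient along x
  sy <- t(sx)
  gx <- conv3x3(pad, sx)[2:(nr + 1L), 2:(nc + 1L)]
  gy <- conv3x3(pad, sy)[2:(nr + 1L), 2:(nc + 1L)]
  (sqrt(gx^2 + gy^2) > 0) + 0L
}

#' 3x3 majority fill
#'
#' Output pixel is 1 iff the 3x3 neighbourhood sum of the input (zero
#' padded at the borders) exceeds 5.
#'
#' @param img binary matrix
#' @return binary integer matrix
#' @export
majorityFill <- function(img) {
  (neighborSum3x3((img > 0) + 0L) > 5) + 0L
}

#' Consolidate an edge image into solid object masks
#'
#' Applies, in order: morphological closing with a disk of radius 9;
#' binary reconstruction using the closed image as marker and the
#' difference mask as mask; geodesic dilation with a 25-px square
#' structuring element (merging fragments of one object into a single
#' connected component); 8-connected hole filling; and one thinning pass
#' to shave residual noise.
#'
#' @param img binary matrix (typically the majority-filled edge image)
#' @param diff the originating \linkS4class{DifferenceMask}
#' @param diskRadius closing disk radius in pixels
#' @param squareWidth geodesic dilation structuring-element width
#' @return binary integer matrix
#' @export
consolidateMask <- function(img, diff, diskRadius = 9L, squareWidth = 25L) {
  m <- (img > 0) + 0L
  if (sum(m) == 0L) return(matrix(0L, nrow(m), ncol(m)))
  dmask <- if (is(diff, "DifferenceMask")) diff@mask else (diff > 0) + 0L
  closed <- EBImage::closing(m, EBImage::makeBrush(2L * diskRadius + 1L,
                                                   "disc"))
  recon <- binaryReconstruct(closed, dmask)
  if (sum(recon) == 0L) recon <- closed    # difference mask fully absorbed
  dil <- EBImage::dilate(recon, EBImage::makeBrush(squareWidth, "box"))
  merged <- binaryReconstruct(recon, dil)
  filled <- EBImage::fillHull(merged)
  zhangSuenThin(filled, iterations = 1L)
}

#' Extract blobs from a binary image
#'
#' Labels 8-connected components, removes those below the component-size
#' floor, and reports per-blob pixel count, centroid (arithmetic mean of
#' member pixel coordinates, 0-based) and tight bounding box.
#'
#' @param img binary matrix
#' @param minComponentSize smallest conserved component, in pixels
#' @return data.frame with columns label, pixel_count, cx, cy, bx, by,
#'   bw, bh (bounding box origin 0-based)
#' @export
extractBlobs <- function(img, minComponentSize = 375L) {
  empty <- data.frame(label = integer(0), pixel_count = integer(0),
                      cx = numeric(0), cy = numeric(0), bx = numeric(0),
                      by = numeric(0), bw = numeric(0), bh = numeric(0))
  m <- (img > 0) + 0L
  if (sum(m) == 0L) return(empty)
  lbl <- label8(m)
  counts <- tabulate(lbl[lbl > 0L])
  keep <- which(counts >= minComponentSize)
  if (length(keep) == 0L) return(empty)
  out <- empty
  nz <- which(lbl > 0L, arr.ind = TRUE)
  lab <- lbl[lbl > 0L]
  newLabel <- 0L
  for (k in keep) {
    sel <- lab == k
    xs <- nz[sel, 1L] - 1L   # 0-based pixel coordinates
    ys <- nz[sel, 2L] - 1L
    newLabel <- newLabel + 1L
    out <- rbind(out, data.frame(
      label = newLabel, pixel_count = counts[k],
      cx = mean(xs), cy = mean(ys),
      bx = min(xs), by = min(ys),
      bw = max(xs) - min(xs) + 1L, bh = max(ys) - min(ys) + 1L))
  }
  out
}

#' Segment one consecutive frame pair into blobs
#'
#' Runs the full chain (difference mask, edge enhancement, majority fill,
#' consolidation, blob extraction) on frames i-1 and i of a sequence.
#'
#' @param prev,cur consecutive infrared frames (integer matrices)
#' @param config pipeline configuration, see \code{\link{defaultConfig}}
#' @return list with elements \code{blobs} (data.frame, empty when the
#'   frame is unevaluable), \code{evaluable}, and \code{stages} (NULL
#'   unless \code{config$debug_stages})
#' @export
segmentFramePair <- function(prev, cur, config = defaultConfig()) {
  dm <- differenceMask(cur, prev,
                       pixelThreshold = config$pixel_threshold,
                       frameThreshold = config$frame_threshold)
  if (!dm@evaluable || dm@foregroundCount == 0L)
    return(list(blobs = extractBlobs(matrix(0L, 1, 1)),
                evaluable = dm@evaluable, stages = NULL))
  # the chain only acts within kernel reach of the difference foreground;
  # restrict computation to that extent (zero padding is preserved by a
  # margin wider than any structuring element)
  margin <- config$square_width + 2L * config$disk_radius + 4L
  nz <- which(dm@mask > 0L, arr.ind = TRUE)
  x0 <- max(1L, min(nz[, 1L]) - margin)
  x1 <- min(nrow(dm@mask), max(nz[, 1L]) + margin)
  y0 <- max(1L, min(nz[, 2L]) - margin)
  y1 <- min(ncol(dm@mask), max(nz[, 2L]) + margin)
  sub <- dm@mask[x0:x1, y0:y1, drop = FALSE]
  edges <- edgeEnhance(sub)
  maj <- majorityFill(edges)
  cons <- consolidateMask(maj, sub, diskRadius = config$disk_radius,
                          squareWidth = config$square_width)
  blobs <- extractBlobs(cons, minComponentSize = config$min_component)
  if (nrow(blobs) > 0L) {
    blobs$cx <- blobs$cx + (x0 - 1L)
    blobs$cy <- blobs$cy + (y0 - 1L)
    blobs$bx <- blobs$bx + (x0 - 1L)
    blobs$by <- blobs$by + (y0 - 1L)
  }
  stages <- NULL
  if (isTRUE(config$debug_stages)) {
    full <- function(m) {
      out <- matrix(0L, nrow(dm@mask), ncol(dm@mask))
      out[x0:x1, y0:y1] <- m
      out
    }
    stages <- list(difference = dm@mask, edges = full(edges),
                   majority = full(maj), consolidated = full(cons))
  }
  list(blobs = blobs, evaluable = TRUE, stages = stages)
}

#' Write the intermediate stages of the segmentation chain as PNGs
#'
#' Debugging analogue of the stage-by-stage figures produced during
#' development: each stage is written as an 8-bit PNG.
#'
#' @param stages list as returned by \code{segmentFramePair} with
#'   \code{debug_stages = TRUE}
#' @param dir output directory
#' @export
writeStagePngs <- function(stages, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(stages))
    png::writePNG(t(stages[[nm]]), file.path(dir, paste0(nm, ".png")))
  invisible(dir)
}
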