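# Raw ".k3dv" container and image-sequence directory I/O.
#
# Container layout (little-endian throughout):
#   magic "K3DV" (4 bytes), uint32 version = 1,
#   uint32 width, uint32 height, uint32 frame_count,
#   then per frame: uint64 timestamp_ms,
#   infrared payload, depth payload (row-major uint16).

K3DV_MAGIC <- charToRaw("K3DV")
K3DV_VERSION <- 1L

# Pack a uint16 matrix into little-endian raw bytes (row-major: x fastest).
packUint16 <- function(m) {
  v <- as.integer(m)                      # column of our width x height
  as.raw(rbind(v %% 256L, v %/% 256L))
}

unpackUint16 <- function(r, width, height) {
  v <- readBin(r, "integer", n = width * height, size = 2L,
               signed = FALSE, endian = "little")
  matrix(v, width, height)
}

writeUint32 <- function(con, x)
  writeBin(as.integer(x), con, size = 4L, endian = "little")

writeUint64 <- function(con, x) {
  # values stay far below 2^53; split into lo/hi uint32 words
  x <- round(x)
  loval <- x %% 2^32
  lo <- as.integer(loval - if (loval >= 2^31) 2^32 else 0)
  hi <- as.integer(x %/% 2^32)
  writeBin(lo, con, size = 4L, endian = "little")
  writeBin(hi, con, size = 4L, endian = "little")
}

readUint32 <- function(con, n = 1L)
  readBin(con, "integer", n = n, size = 4L, endian = "little")

readUint64 <- function(con) {
  w <- readBin(con, "integer", n = 2L, size = 4L, endian = "little")
  lo <- ifelse(w[1] < 0, w[1] + 2^32, w[1])
  lo + w[2] * 2^32
}

#' Write a frame sequence to a .k3dv container
#'
#' @param frames a \linkS4class{FrameSequence} (non-empty)
#' @param path output file path
#' @return \code{path}, invisibly
#' @export
writeFrameSequence <- function(frames, path) {
  stopifnot(is(frames, "FrameSequence"))
  n <- nFrames(frames)
  if (n == 0L) stop("cannot write an empty frame sequence")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(K3DV_MAGIC, con)
  writeUint32(con, K3DV_VERSION)
  writeUint32(con, frames@width)
  writeUint32(con, frames@height)
  writeUint32(con, n)
  for (i in seq_len(n)) {
    writeUint64(con, frames@timestamps[i])
    writeBin(packUint16(frames@infrared[[i]]), con)
    writeBin(packUint16(frames@depth[[i]]), con)
  }
  invisible(path)
}

#' Read a frame sequence
#'
#' Reads either a .k3dv container written by \code{\link{writeFrameSequence}}
#' or a directory of paired 16-bit TIFF/PNG images named
#' \code{ir_\%06d.tif} / \code{depth_\%06d.tif} (or .png) with a
#' \code{timestamps.csv} file (columns frame, timestamp_ms).
#'
#' @param path container file or image-sequence directory
#' @return a \linkS4class{FrameSequence}
#' @export
readFrameSequence <- function(path) {
  if (dir.exists(path)) return(readFrameDirectory(path))
  if (!file.exists(path)) stop("no such file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", n = 4L)
  if (!identical(magic, K3DV_MAGIC))
    stop("not a k3dv container (bad magic)")
  ver <- readUint32(con)
  if (!identical(ver, K3DV_VERSION))
    stop("unsupported k3dv version: ", ver)
  width <- readUint32(con); height <- readUint32(con)
  n <- readUint32(con)
  np <- width * height
  ir <- vector("list", n); dp <- vector("list", n); ts <- numeric(n)
  for (i in seq_len(n)) {
    ts[i] <- tryCatch(readUint64(con), error = function(e) NA_real_)
    irraw <- readBin(con, "raw", n = 2L * np)
    dpraw <- readBin(con, "raw", n = 2L * np)
    if (is.na(ts[i]) || length(irraw) < 2L * np || length(dpraw) < 2L * np)
      stop(sprintf("k3dv container truncated at frame %d", i))
    ir[[i]] <- unpackUint16(irraw, width, height)
    dp[[i]] <- unpackUint16(dpraw, width, height)
  }
  new("FrameSequence", infrared = ir, depth = dp, timestamps = ts,
      width = as.integer(width), height = as.integer(height))
}

readImage16 <- function(path) {
  x <- if (grepl("\\.png$", path, ignore.case = TRUE)) {
    round(png::readPNG(path) * 65535)
  } else {
    y <- tiff::readTIFF(path, as.is = TRUE)
    if (max(y) <= 1) round(y * 65535) else y
  }
  # image files are stored [row = y, col = x]; internal layout is x-major
  t(matrix(as.integer(x), nrow(x), ncol(x)))
}

readFrameDirectory <- function(path) {
  irf <- sort(list.files(path, "^ir_[0-9]{6}\\.(tif|tiff|png)$",
                         full.names = TRUE))
  dpf <- sort(list.files(path, "^depth_[0-9]{6}\\.(tif|tiff|png)$",
                         full.names = TRUE))
  if (length(irf) == 0L) stop("no ir_%06d images found in ", path)
  if (length(irf) != length(dpf))
    stop("unpaired infrared/depth images in ", path)
  tsf <- file.path(path, "timestamps.csv")
  ts <- if (file.exists(tsf)) {
    tab <- utils::read.csv(tsf)
    tab$timestamp_ms[order(tab$frame)]
  } else {
    (seq_along(irf) - 1L) * (1000 / FPS)
  }
  ir <- lapply(irf, readImage16)
  dp <- lapply(dpf, readImage16)
  new("FrameSequence", infrared = ir, depth = dp,
      timestamps = as.numeric(ts[seq_along(irf)]),
      width = nrow(ir[[1]]), height = ncol(ir[[1]]))
}

#' Write a frame sequence as a 16-bit TIFF image directory
#'
#' Companion to the directory form accepted by
#' \code{\link{readFrameSequence}}.
#'
#' @param frames a \linkS4class{FrameSequence}
#' @param dir output directory (created if needed)
#' @return \code{dir}, invisibly
#' @export
writeFrameDirectory <- function(frames, dir) {
  stopifnot(is(frames, "FrameSequence"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_len(nFrames(frames))) {
    tiff::writeTIFF(t(frames@infrared[[i]]) / 65535,
                    file.path(dir, sprintf("ir_%06d.tif", i)),
                    bits.per.sample = 16L)
    tiff::writeTIFF(t(frames@depth[[i]]) / 65535,
                    file.path(dir, sprintf("depth_%06d.tif", i)),
                    bits.per.sample = 16L)
  }
  utils::write.csv(
    data.frame(frame = seq_len(nFrames(frames)),
               timestamp_ms = frames@timestamps),
    file.path(dir, "timestamps.csv"), row.names = FALSE)
  invisible(dir)
}
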