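# Persistent blob identities across frames: greedy nearest-centroid
# association with a distance gate, per-track constant-velocity Kalman
# smoothing, and windowed depth lookup at each centroid.

#' Depth reading near a centroid
#'
#' Returns the depth value at the rounded centroid if nonzero; otherwise
#' grows a square search window (3x3, 5x5, ... up to \code{maxWindow})
#' and returns the nonzero value nearest the centroid in Euclidean
#' distance (ties broken in raster-scan order). \code{NA} when no nonzero
#' value exists within the maximum window.
#'
#' @param depthFrame integer matrix of depth values (mm, 0 = no reading)
#' @param centroid numeric (x, y), 0-based pixel coordinates
#' @param maxWindow odd maximum window width in pixels
#' @return depth in mm, or \code{NA}
#' @export
depthLookup <- function(depthFrame, centroid, maxWindow = 21L) {
  stopifnot(maxWindow %% 2L == 1L)
  cx <- round(centroid[1]) + 1L    # to 1-based indices
  cy <- round(centroid[2]) + 1L
  nr <- nrow(depthFrame); nc <- ncol(depthFrame)
  if (cx < 1L || cx > nr || cy < 1L || cy > nc)
    stop("centroid outside the frame")
  if (depthFrame[cx, cy] > 0L) return(depthFrame[cx, cy])
  for (half in seq_len((maxWindow - 1L) / 2L)) {
    xs <- max(1L, cx - half):min(nr, cx + half)
    ys <- max(1L, cy - half):min(nc, cy + half)
    win <- depthFrame[xs, ys, drop = FALSE]
    nzi <- which(win > 0L, arr.ind = TRUE)
    if (nrow(nzi) > 0L) {
      dx <- xs[nzi[, 1L]] - cx
      dy <- ys[nzi[, 2L]] - cy
      d2 <- dx^2 + dy^2
      # raster-scan tie break: order by distance, then y, then x
      ord <- order(d2, ys[nzi[, 2L]], xs[nzi[, 1L]])
      return(win[nzi[ord[1L], 1L], nzi[ord[1L], 2L]])
    }
  }
  NA_integer_
}

# Constant-velocity Kalman filter over (x, y); state (x, y, vx, vy).
kalmanCreate <- function(x, y, processNoise = 1, measurementNoise = 4,
                         p0 = 100) {
  list(state = c(x, y, 0, 0), P = diag(4) * p0,
       Q = diag(4) * processNoise, R = diag(2) * measurementNoise)
}

kalmanStep <- function(kf, obs = NULL) {
  FF <- diag(4); FF[1, 3] <- 1; FF[2, 4] <- 1   # dt = 1 frame
  H <- matrix(0, 2, 4); H[1, 1] <- 1; H[2, 2] <- 1
  kf$state <- as.numeric(FF %*% kf$state)
  kf$P <- FF %*% kf$P %*% t(FF) + kf$Q
  if (!is.null(obs)) {
    S <- H %*% kf$P %*% t(H) + kf$R
    K <- kf$P %*% t(H) %*% solve(S)
    kf$state <- as.numeric(kf$state + K %*% (obs - H %*% kf$state))
    kf$P <- (diag(4) - K %*% H) %*% kf$P
  }
  kf
}

#' Associate per-frame blobs into tracks
#'
#' Greedy nearest-centroid assignment between each frame's blobs and the
#' Kalman-predicted positions of open tracks, gated at
#' \code{gate} pixels/frame. Unmatched blobs open new tracks with fresh
#' numeric identifiers; tracks unmatched for more than \code{maxMisses}
#' consecutive frames are closed. Smoothed centroids come from a
#' per-track constant-velocity Kalman filter.
#'
#' @param blobFrames list with one element per frame: a list with
#'   \code{timestamp_ms}, \code{frame} (index), \code{blobs} (data.frame
#'   from \code{\link{extractBlobs}}), and optionally \code{depth}
#'   (the depth frame) and \code{ir} (the infrared frame) used to attach
#'   per-entry depth and intensity readings
#' @param gate association gate in pixels/frame
#' @param maxMisses frames a track may go unmatched before closing
#' @param processNoise,measurementNoise Kalman noise parameters (px^2)
#' @param depthWindow maximum depth search window (odd, px)
#' @return a \linkS4class{TrackSet}
#' @export
associateTracks <- function(blobFrames, gate = 50, maxMisses = 15L,
                            processNoise = 1, measurementNoise = 4,
                            depthWindow = 21L) {
  nextId <- 1L
  open <- list()     # id -> list(kf, misses, rows)
  done <- list()
  firstSeen <- numeric(0)

  closeTrack <- function(id) {
    done[[id]] <<- open[[id]]$rows
    open[[id]] <<- NULL
  }

  for (fr in blobFrames) {
    blobs <- fr$blobs
    nb <- if (is.null(blobs)) 0L else nrow(blobs)
    # predict all open tracks
    preds <- lapply(open, function(tr) {
      kf <- kalmanStep(tr$kf, NULL)   # prediction only (no update yet)
      kf$state[1:2]
    })
    assignedTrack <- rep(NA_character_, nb)
    if (nb > 0L && length(open) > 0L) {
      ids <- names(open)
      cost <- matrix(Inf, nb, length(ids))
      for (j in seq_along(ids))
        cost[, j] <- sqrt((blobs$cx - preds[[j]][1])^2 +
                          (blobs$cy - preds[[j]][2])^2)
      repeat {
        mi <- which(cost == min(cost), arr.ind = TRUE)
        if (!is.finite(min(cost)) || min(cost) > gate) break
        b <- mi[1, 1]; j <- mi[1, 2]
        assignedTrack[b] <- ids[j]
        cost[b, ] <- Inf; cost[, j] <- Inf
      }
    }
    # update matched tracks, grow rows
    for (b in seq_len(nb)) {
      id <- assignedTrack[b]
      obs <- c(blobs$cx[b], blobs$cy[b])
      if (is.na(id)) {
        id <- as.character(nextId)
        nextId <- nextId + 1L
        open[[id]] <- list(kf = kalmanCreate(obs[1], obs[2], processNoise,
                                             measurementNoise),
                           misses = 0L, rows = NULL)
        firstSeen[id] <- fr$timestamp_ms
        open[[id]]$kf <- kalmanStep(open[[id]]$kf, obs)
      } else {
        open[[id]]$kf <- kalmanStep(open[[id]]$kf, obs)
        open[[id]]$misses <- 0L
      }
      st <- open[[id]]$kf$state
      depth <- NA_integer_; irv <- NA_integer_
      if (!is.null(fr$depth))
        depth <- depthLookup(fr$depth, obs, maxWindow = depthWindow)
      if (!is.null(fr$ir))
        irv <- fr$ir[round(obs[1]) + 1L, round(obs[2]) + 1L]
      open[[id]]$rows <- rbind(open[[id]]$rows, data.frame(
        timestamp_ms = fr$timestamp_ms, frame = fr$frame,
        cx_raw = obs[1], cy_raw = obs[2], cx = st[1], cy = st[2],
        bx = blobs$bx[b], by = blobs$by[b], bw = blobs$bw[b],
        bh = blobs$bh[b], ir = irv, depth_mm = depth))
    }
    # age unmatched tracks
    matched <- assignedTrack[!is.na(assignedTrack)]
    for (id in setdiff(names(open), matched)) {
      # skip tracks opened this frame
      if (nrow(open[[id]]$rows) > 0L &&
          open[[id]]$rows$timestamp_ms[nrow(open[[id]]$rows)] ==
            fr$timestamp_ms) next
      open[[id]]$misses <- open[[id]]$misses + 1L
      open[[id]]$kf <- kalmanStep(open[[id]]$kf, NULL)
      if (open[[id]]$misses > maxMisses) closeTrack(id)
    }
  }
  for (id in names(open)) closeTrack(id)
  ord <- order(as.integer(names(done)))
  done <- done[ord]
  new("TrackSet", tracks = done,
      firstSeen = unname(firstSeen[names(done)]))
}

#' Keep only whitelisted (child) tracks
#'
#' Identifiers assigned to other persons in frame are excluded by keeping
#' only a reviewed whitelist of track ids, concatenated per child in time
#' order (a child who re-entered the scene under a new id is merged).
#'
#' @param trackSet a \linkS4class{TrackSet}
#' @param idWhitelist character or integer vector of track ids to keep
#' @return a single time-ordered data.frame of track entries
#' @export
selectChildTracks <- function(trackSet, idWhitelist) {
  stopifnot(length(idWhitelist) > 0L)
  ids <- as.character(idWhitelist)
  missing <- setdiff(ids, trackIds(trackSet))
  if (length(missing) > 0L)
    warning("whitelisted track id(s) not present: ",
            paste(missing, collapse = ", "))
  keep <- intersect(ids, trackIds(trackSet))
  if (length(keep) == 0L)
    return(data.frame())
  out <- do.call(rbind, trackData(trackSet)[keep])
  out <- out[order(out$timestamp_ms), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Extract tracks from a frame sequence
#'
#' Convenience wrapper: segments every consecutive frame pair and
#' associates the resulting blobs into tracks.
#'
#' @param frames a \linkS4class{FrameSequence}
#' @param config pipeline configuration, see \code{\link{defaultConfig}}
#' @return a \linkS4class{TrackSet}
#' @export
extractTracks <- function(frames, config = defaultConfig()) {
  n <- nFrames(frames)
  blobFrames <- vector("list", max(0L, n - 1L))
  for (i in seq_len(n - 1L) + 1L) {
    seg <- segmentFramePair(irFrame(frames, i - 1L), irFrame(frames, i),
                            config)
    blobFrames[[i - 1L]] <- list(
      timestamp_ms = frameTimes(frames)[i], frame = i,
      blobs = if (seg$evaluable) seg$blobs else seg$blobs[0, ],
      depth = depthFrame(frames, i), ir = irFrame(frames, i))
  }
  associateTracks(blobFrames, gate = config$gate_px,
                  maxMisses = config$max_misses,
                  processNoise = config$kalman_process_noise,
                  measurementNoise = config$kalman_measurement_noise,
                  depthWindow = config$depth_window)
}

#' Write tracks as JSON lines
#'
#' One JSON object per track entry (frame observation).
#'
#' @param trackSet a \linkS4class{TrackSet}
#' @param path output file
#' @export
writeTracks <- function(trackSet, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (id in trackIds(trackSet)) {
    tr <- trackData(trackSet)[[id]]
    for (i in seq_len(nrow(tr))) {
      rec <- c(list(track_id = id), as.list(tr[i, ]))
      writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA,
                                  na = "null"), con)
    }
  }
  invisible(path)
}
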