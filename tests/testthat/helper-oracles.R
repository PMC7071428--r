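# Independent oracles and fixture builders used across the suite.
# Every oracle is a deliberately naive implementation (loops, direct
# counting) kept separate from the package's own code paths.

# Naive 3x3 convolution by explicit looping (zero padded).
oracleConv3x3 <- function(m, kernel) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    acc <- 0
    for (di in -1:1) for (dj in -1:1) {
      ii <- i - di; jj <- j - dj
      v <- if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc) m[ii, jj] else 0
      acc <- acc + kernel[di + 2, dj + 2] * v
    }
    out[i, j] <- acc
  }
  out
}

# Replicate (clamp) padding by one pixel on every side.
padReplicate <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  p <- matrix(0L, nr + 2L, nc + 2L)
  p[2:(nr + 1L), 2:(nc + 1L)] <- m
  p[1L, ] <- p[2L, ]; p[nr + 2L, ] <- p[nr + 1L, ]
  p[, 1L] <- p[, 2L]; p[, nc + 2L] <- p[, nc + 1L]
  p
}

# Brute-force AUC: count concordant positive/negative pairs, ties half.
oracleAuc <- function(scores, positive) {
  ps <- scores[positive]; ns <- scores[!positive]
  tot <- 0
  for (p in ps) for (q in ns)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(ps) * length(ns))
}

# ICC(2,1) via aov mean squares (independent decomposition route).
oracleIcc <- function(a, b) {
  n <- length(a)
  long <- data.frame(score = c(a, b),
                     subject = factor(rep(seq_len(n), 2L)),
                     rater = factor(rep(1:2, each = n)))
  ms <- anova(stats::lm(score ~ subject + rater, data = long))
  msr <- ms["subject", "Mean Sq"]
  msc <- ms["rater", "Mean Sq"]
  mse <- ms["Residuals", "Mean Sq"]
  (msr - mse) / (msr + mse + 2 * (msc - mse) / n)
}

# Finite-difference velocity oracle on a window of positions
# (axis units per second).
oracleFiniteDiff <- function(positions, dt = 1 / 30) {
  ok <- which(!is.na(positions))
  if (length(ok) < 2L) return(NA_real_)
  span <- ok[length(ok)] - ok[1L]
  (positions[ok[length(ok)]] - positions[ok[1L]]) / span / dt
}

# Build synthetic per-frame blob lists for tracking tests without
# rendering: `paths` is a list of data.frames (frame, cx, cy).
makeBlobFrames <- function(paths, nFrames, fps = 30) {
  lapply(seq_len(nFrames), function(k) {
    rows <- NULL
    for (p in paths) {
      hit <- p[p$frame == k, ]
      if (nrow(hit) == 1L)
        rows <- rbind(rows, data.frame(
          label = 1L, pixel_count = 400L, cx = hit$cx, cy = hit$cy,
          bx = hit$cx - 10, by = hit$cy - 10, bw = 20, bh = 20))
    }
    list(timestamp_ms = round((k - 1) * 1000 / fps), frame = k,
         blobs = if (is.null(rows)) data.frame() else rows)
  })
}

# Small rendered fixture cache so several tests can share one render.
localFixtureCache <- new.env(parent = emptyenv())
renderedFixture <- function(key, maker) {
  if (is.null(localFixtureCache[[key]]))
    localFixtureCache[[key]] <- maker()
  localFixtureCache[[key]]
}

# Shared fixtures
movingSquareFixture <- function() renderedFixture("movingSquare", function() {
  sq <- trajectoryScript("sq", shapeWidth = 40, shapeHeight = 40,
    path = data.frame(t_ms = c(0, 800), x_px = c(60, 540), y_px = 240,
                      depth_mm = 2000))
  renderSequence(sq, duration_s = 0.8, noise_sd = 0, seed = 1)
})

# 1 m/s straight-line slab at 3000 mm, 2 s (no direction reversals)
slabFixture <- function() renderedFixture("slab1mps", function() {
  sc <- makeConstantVelocityScript(1.0, "x", depth_mm = 3000,
                                   duration_s = 2, style = "straight")
  renderSequence(sc, 2, 0, 1)
})
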