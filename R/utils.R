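# Internal helpers shared across the segmentation and motion code.

# Shift a matrix by (dx, dy) with zero padding. dx moves content toward
# higher row indices (x axis), dy toward higher column indices (y axis).
shiftMat <- function(m, dx, dy) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0, nr, nc)
  xs <- seq_len(nr); ys <- seq_len(nc)
  xsrc <- xs - dx; ysrc <- ys - dy
  okx <- xsrc >= 1L & xsrc <= nr
  oky <- ysrc >= 1L & ysrc <= nc
  out[xs[okx], ys[oky]] <- m[xsrc[okx], ysrc[oky]]
  out
}

# 3x3 convolution with zero padding, kernel given as a 3x3 matrix indexed
# [dx+2, dy+2]. Implemented as shift-and-add; exact on the borders.
conv3x3 <- function(m, kernel) {
  out <- matrix(0, nrow(m), ncol(m))
  for (dx in -1:1) for (dy in -1:1) {
    k <- kernel[dx + 2L, dy + 2L]
    if (k != 0) out <- out + k * shiftMat(m, dx, dy)
  }
  out
}

# Sum of the 3x3 neighbourhood of every pixel (zero padded).
neighborSum3x3 <- function(m) conv3x3(m, matrix(1, 3, 3))

# 8-connected labelling. EBImage::bwlabel is 4-connected; labels that touch
# diagonally are merged through a components pass on the label adjacency
# graph.
label8 <- function(x) {
  lbl <- EBImage::bwlabel(x)
  n <- max(lbl)
  if (n <= 1L) return(lbl)
  pairs <- NULL
  for (dd in list(c(1L, 1L), c(1L, -1L))) {
    a <- lbl[seq_len(nrow(lbl) - 1L), , drop = FALSE]
    b <- lbl[seq_len(nrow(lbl) - 1L) + 1L, , drop = FALSE]
    if (dd[2L] == 1L) {
      a <- a[, seq_len(ncol(lbl) - 1L), drop = FALSE]
      b <- b[, seq_len(ncol(lbl) - 1L) + 1L, drop = FALSE]
    } else {
      a <- a[, seq_len(ncol(lbl) - 1L) + 1L, drop = FALSE]
      b <- b[, seq_len(ncol(lbl) - 1L), drop = FALSE]
    }
    sel <- a > 0L & b > 0L & a != b
    if (any(sel)) pairs <- rbind(pairs, cbind(a[sel], b[sel]))
  }
  if (is.null(pairs)) return(lbl)
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  g <- igraph::add_edges(g, t(unique(pairs)))
  comp <- igraph::components(g)$membership
  out <- matrix(0L, nrow(lbl), ncol(lbl))
  nz <- lbl > 0L
  out[nz] <- comp[lbl[nz]]
  # deterministic renumbering by first occurrence in scan order
  u <- unique(out[nz])
  relab <- integer(max(u))
  relab[u] <- seq_along(u)
  out[nz] <- relab[out[nz]]
  out
}

# Binary morphological reconstruction: keep the connected components of
# `mask` that intersect `marker` (exact for binary images).
binaryReconstruct <- function(marker, mask) {
  lbl <- label8(mask)
  keep <- unique(lbl[marker > 0 & lbl > 0L])
  out <- matrix(0L, nrow(mask), ncol(mask))
  if (length(keep)) out[lbl %in% keep] <- 1L
  out
}

# One pass of Zhang-Suen thinning (both subiterations), vectorised.
zhangSuenThin <- function(x, iterations = 1L) {
  x <- (x > 0) + 0L
  for (it in seq_len(iterations)) {
    for (sub in 1:2) {
      p2 <- shiftMat(x, 0, -1); p3 <- shiftMat(x, 1, -1)
      p4 <- shiftMat(x, 1, 0);  p5 <- shiftMat(x, 1, 1)
      p6 <- shiftMat(x, 0, 1);  p7 <- shiftMat(x, -1, 1)
      p8 <- shiftMat(x, -1, 0); p9 <- shiftMat(x, -1, -1)
      b <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      seqs <- list(p2, p3, p4, p5, p6, p7, p8, p9, p2)
      a <- matrix(0L, nrow(x), ncol(x))
      for (i in 1:8) a <- a + (seqs[[i]] == 0L & seqs[[i + 1L]] == 1L)
      if (sub == 1L) {
        c1 <- p2 * p4 * p6; c2 <- p4 * p6 * p8
      } else {
        c1 <- p2 * p4 * p8; c2 <- p2 * p6 * p8
      }
      del <- x == 1L & b >= 2L & b <= 6L & a == 1L & c1 == 0L & c2 == 0L
      x[del] <- 0L
    }
  }
  x
}

clipUint16 <- function(x) {
  x[x < 0] <- 0
  x[x > 65535] <- 65535
  x
}

standardGravity <- 9.80665
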