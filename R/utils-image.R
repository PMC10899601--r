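# Internal image helpers. Images are numeric arrays [h, w, 3] in [0, 1];
# masks are logical matrices [h, w]. Coordinates are 0-based, origin top-left.

clamp01 <- function(x) pmin(pmax(x, 0), 1)

# Deterministic child seed so per-slide / per-stage streams are independent
# of each other but pure functions of the master seed. Kept below 2^31.
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) %% 2147483647 + 999983 * (as.numeric(k) %% 1024) + 1) %% 2147483647)
}

#' @noRd
as_rgb_array <- function(x) {
  if (length(dim(x)) == 2L) {
    x <- array(rep(x, 3L), c(dim(x), 3L))
  }
  if (length(dim(x)) == 3L && dim(x)[3] == 4L) x <- x[, , 1:3, drop = FALSE]
  stopifnot(length(dim(x)) == 3L, dim(x)[3] == 3L)
  x
}

# Area-average downsample by an integer factor; trims a partial border.
block_downsample <- function(img, f) {
  f <- as.integer(f)
  if (f == 1L) return(img)
  d <- dim(img)
  nc <- if (length(d) == 3L) d[3] else 1L
  h2 <- d[1] %/% f
  w2 <- d[2] %/% f
  a <- array(img, c(d[1], d[2], nc))[seq_len(h2 * f), seq_len(w2 * f), , drop = FALSE]
  dim(a) <- c(f, h2, f * w2 * nc)
  a <- colMeans(a)                        # (h2, f*w2*nc)
  dim(a) <- c(h2, f, w2 * nc)
  a <- aperm(a, c(2L, 1L, 3L))
  dim(a) <- c(f, h2 * w2 * nc)
  a <- colMeans(a)
  out <- array(a, c(h2, w2, nc))
  if (length(d) == 2L) out <- out[, , 1L] else out
}

# Bilinear resize with half-pixel center alignment.
resize_bilinear <- function(img, oh, ow) {
  d <- dim(img)
  two_d <- length(d) == 2L
  if (two_d) img <- array(img, c(d, 1L))
  ih <- dim(img)[1]; iw <- dim(img)[2]; nc <- dim(img)[3]
  ys <- (seq_len(oh) - 0.5) * ih / oh + 0.5
  xs <- (seq_len(ow) - 0.5) * iw / ow + 0.5
  y0 <- pmin(pmax(floor(ys), 1), ih); y1 <- pmin(y0 + 1, ih)
  x0 <- pmin(pmax(floor(xs), 1), iw); x1 <- pmin(x0 + 1, iw)
  wy <- matrix(pmin(pmax(ys - y0, 0), 1), oh, ow)
  wx <- matrix(pmin(pmax(xs - x0, 0), 1), oh, ow, byrow = TRUE)
  out <- array(0, c(oh, ow, nc))
  for (k in seq_len(nc)) {
    ch <- img[, , k]
    out[, , k] <- ch[y0, x0] * (1 - wy) * (1 - wx) + ch[y0, x1] * (1 - wy) * wx +
      ch[y1, x0] * wy * (1 - wx) + ch[y1, x1] * wy * wx
  }
  if (two_d) out[, , 1L] else out
}

# HSV saturation channel of an RGB array: (max - min) / max, 0 where max = 0.
rgb_saturation <- function(img) {
  img <- as_rgb_array(img)
  mx <- pmax(img[, , 1], img[, , 2], img[, , 3])
  mn <- pmin(img[, , 1], img[, , 2], img[, , 3])
  s <- (mx - mn) / mx
  s[mx == 0] <- 0
  s
}

# Pad an image (or mask) on the bottom/right with a constant so both
# dimensions become multiples of `f`.
pad_to_multiple <- function(img, f, value = 1) {
  d <- dim(img)
  h2 <- ceiling(d[1] / f) * f
  w2 <- ceiling(d[2] / f) * f
  if (h2 == d[1] && w2 == d[2]) return(img)
  if (length(d) == 2L) {
    out <- matrix(value, h2, w2)
    out[seq_len(d[1]), seq_len(d[2])] <- img
  } else {
    out <- array(value, c(h2, w2, d[3]))
    out[seq_len(d[1]), seq_len(d[2]), ] <- img
  }
  out
}

# Smooth random field in [0,1]^2: coarse iid normal grid, bilinear-upsampled.
smooth_field <- function(px, coarse = 6L) {
  g <- matrix(stats::rnorm(coarse * coarse), coarse, coarse)
  resize_bilinear(g, px, px)
}

# Quantize to 8-bit so the in-memory raster equals its PNG round-trip.
quantize8 <- function(img) round(clamp01(img) * 255) / 255
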