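# Small convolutional tile encoder with manual forward/backward passes.
#
# Architecture (desk scale): 3x3 valid convolution (C filters) -> ReLU ->
# 2x2 mean pool -> flatten -> fully connected embedding h (dim d), followed
# by a projection head of two fully connected layers (ReLU between) whose
# output z is L2-normalized for the contrastive loss.  The projection head
# is used only during pretraining; feature extraction returns h.
#
# All tensors are plain matrices; convolution is im2col + matrix multiply.

.encoder_config <- function(in_px = 32L, conv_channels = 8L, embed_dim = 32L,
                            proj_dim = 16L) {
  in_px <- as.integer(in_px)
  if (in_px < 6L || (in_px - 2L) %% 2L != 0L)
    stop("in_px must be even and at least 6 (3x3 valid conv then 2x2 pool)")
  q <- in_px - 2L
  list(in_px = in_px, C = as.integer(conv_channels), d = as.integer(embed_dim),
       dz = as.integer(proj_dim), q = q, q2 = q %/% 2L,
       fc_in = (q %/% 2L)^2 * as.integer(conv_channels))
}

# im2col gather index for one [p, p, 3] sample (column-major linear indices);
# rows ordered by output position (row index fastest), columns by (di, dj, c).
.im2col_index <- function(p) {
  q <- p - 2L
  I <- rep(seq_len(q), times = q)
  J <- rep(seq_len(q), each = q)
  idx <- matrix(0L, q * q, 27L)
  col <- 0L
  for (c in 0:2) for (dj in 0:2) for (di in 0:2) {
    col <- col + 1L
    idx[, col] <- (I + di) + (J + dj - 1L) * p + c * p * p
  }
  idx
}

.encoder_init <- function(cfg, seed = 1L) {
  set.seed(seed)
  he <- function(nr, nc, fan_in) matrix(stats::rnorm(nr * nc, 0, sqrt(2 / fan_in)), nr, nc)
  list(W1 = he(27L, cfg$C, 27), b1 = numeric(cfg$C),
       W2 = he(cfg$fc_in, cfg$d, cfg$fc_in), b2 = numeric(cfg$d),
       Wp1 = he(cfg$d, cfg$d, cfg$d), bp1 = numeric(cfg$d),
       Wp2 = he(cfg$d, cfg$dz, cfg$d), bp2 = numeric(cfg$dz))
}

# Forward pass.  X: [n, p, p, 3].  Returns h (n x d) and, when project=TRUE,
# the normalized projection z (n x dz).  keep_cache retains intermediates
# for the backward pass.
.encoder_forward <- function(par, cfg, X, idx, project = TRUE, keep_cache = FALSE) {
  n <- dim(X)[1]; p <- cfg$in_px; q <- cfg$q; q2 <- cfg$q2; C <- cfg$C
  Xm <- matrix(aperm(X, c(2, 3, 4, 1)), p * p * 3L, n)
  colmat <- Xm[as.vector(idx), , drop = FALSE]       # (q*q*27) x n
  dim(colmat) <- c(q * q, 27L, n)
  colmat <- aperm(colmat, c(1, 3, 2))
  dim(colmat) <- c(q * q * n, 27L)
  Z1 <- colmat %*% par$W1
  Z1 <- Z1 + rep(par$b1, each = nrow(Z1))
  relu_mask <- Z1 > 0
  A1 <- Z1 * relu_mask
  # 2x2 mean pool over the q x q conv grid
  A <- A1; dim(A) <- c(2L, q2, 2L, q2 * n * C)
  A <- colMeans(A); dim(A) <- c(q2, 2L, q2 * n * C)
  A <- aperm(A, c(2, 1, 3)); dim(A) <- c(2L, q2 * q2 * n * C)
  P <- array(colMeans(A), c(q2, q2, n, C))
  Pm <- aperm(P, c(1, 2, 4, 3)); dim(Pm) <- c(cfg$fc_in, n)
  H <- crossprod(Pm, par$W2) + rep(par$b2, each = n)  # n x d
  out <- list(h = H)
  if (project) {
    A2 <- H %*% par$Wp1 + rep(par$bp1, each = n)
    R2 <- pmax(A2, 0)
    Zp <- R2 %*% par$Wp2 + rep(par$bp2, each = n)
    nrm <- sqrt(rowSums(Zp^2)); nrm[nrm < 1e-12] <- 1e-12
    out$z <- Zp / nrm
    if (keep_cache) out$cache <- list(colmat = colmat, relu_mask = relu_mask,
                                      Pm = Pm, H = H, A2 = A2, R2 = R2,
                                      Zp = Zp, nrm = nrm, z = out$z, n = n)
  } else if (keep_cache) {
    out$cache <- list(colmat = colmat, relu_mask = relu_mask, Pm = Pm, H = H, n = n)
  }
  out
}

# Backward pass.  Supply dZ (gradient wrt the normalized projection, n x dz)
# and/or dH (gradient arriving directly at the embedding h, n x d).
.encoder_backward <- function(par, cfg, cache, dZ = NULL, dH = NULL) {
  n <- cache$n; q <- cfg$q; q2 <- cfg$q2; C <- cfg$C
  g <- list()
  dh <- if (is.null(dH)) matrix(0, n, cfg$d) else dH
  if (!is.null(dZ)) {
    zn <- cache$z
    dZp <- (dZ - rowSums(dZ * zn) * zn) / cache$nrm
    g$Wp2 <- crossprod(cache$R2, dZp); g$bp2 <- colSums(dZp)
    dR2 <- tcrossprod(dZp, par$Wp2)
    dA2 <- dR2 * (cache$A2 > 0)
    g$Wp1 <- crossprod(cache$H, dA2); g$bp1 <- colSums(dA2)
    dh <- dh + tcrossprod(dA2, par$Wp1)
  } else {
    g$Wp2 <- par$Wp2 * 0; g$bp2 <- par$bp2 * 0
    g$Wp1 <- par$Wp1 * 0; g$bp1 <- par$bp1 * 0
  }
  g$W2 <- cache$Pm %*% dh; g$b2 <- colSums(dh)
  dPm <- par$W2 %*% t(dh)                              # fc_in x n
  dP <- array(dPm, c(q2, q2, C, n))
  dP <- aperm(dP, c(1, 2, 4, 3))                       # q2, q2, n, C
  dA1 <- dP[rep(seq_len(q2), each = 2L), rep(seq_len(q2), each = 2L), , , drop = FALSE] / 4
  dim(dA1) <- c(q * q * n, C)
  dZ1 <- dA1 * cache$relu_mask
  g$W1 <- crossprod(cache$colmat, dZ1); g$b1 <- colSums(dZ1)
  g
}

.sgd_step <- function(par, grads, vel, lr, momentum, weight_decay) {
  for (nm in names(grads)) {
    gg <- grads[[nm]] + weight_decay * par[[nm]]
    vel[[nm]] <- momentum * vel[[nm]] + gg
    par[[nm]] <- par[[nm]] - lr * vel[[nm]]
  }
  list(par = par, vel = vel)
}

.adam_step <- function(par, grads, st, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  st$t <- st$t + 1L
  for (nm in names(grads)) {
    st$m[[nm]] <- beta1 * st$m[[nm]] + (1 - beta1) * grads[[nm]]
    st$v[[nm]] <- beta2 * st$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    mh <- st$m[[nm]] / (1 - beta1^st$t)
    vh <- st$v[[nm]] / (1 - beta2^st$t)
    par[[nm]] <- par[[nm]] - lr * mh / (sqrt(vh) + eps)
  }
  list(par = par, st = st)
}

.zeros_like <- function(par) lapply(par, function(x) x * 0)

# 3x3 box blur with replicated edges.
.box_blur3 <- function(img) {
  d <- dim(img)
  pad <- array(0, c(d[1] + 2L, d[2] + 2L, d[3]))
  pad[2:(d[1] + 1L), 2:(d[2] + 1L), ] <- img
  pad[1, , ] <- pad[2, , ]; pad[d[1] + 2L, , ] <- pad[d[1] + 1L, , ]
  pad[, 1, ] <- pad[, 2, ]; pad[, d[2] + 2L, ] <- pad[, d[2] + 1L, ]
  out <- array(0, d)
  for (di in 0:2) for (dj in 0:2)
    out <- out + pad[(1:d[1]) + di, (1:d[2]) + dj, , drop = FALSE]
  out / 9
}

# Stochastic augmentation of one tile: random crop-resize, flips, color
# jitter, random grayscale, random box blur.  Consumes the R RNG stream.
.augment_tile <- function(tile, out_px, crop_scale = c(0.2, 1)) {
  p <- dim(tile)[1]
  s <- stats::runif(1, crop_scale[1], crop_scale[2])
  side <- max(4L, min(p, round(p * sqrt(s))))
  y0 <- sample.int(p - side + 1L, 1L); x0 <- sample.int(p - side + 1L, 1L)
  t2 <- tile[y0:(y0 + side - 1L), x0:(x0 + side - 1L), , drop = FALSE]
  t2 <- resize_bilinear(t2, out_px, out_px)
  if (stats::runif(1) < 0.5) t2 <- t2[, rev(seq_len(out_px)), , drop = FALSE]
  if (stats::runif(1) < 0.5) t2 <- t2[rev(seq_len(out_px)), , , drop = FALSE]
  b <- stats::runif(1, 0.75, 1.25)
  t2 <- t2 * b
  m <- mean(t2)
  t2 <- (t2 - m) * stats::runif(1, 0.75, 1.25) + m
  if (stats::runif(1) < 0.2) {
    gr <- (t2[, , 1] + t2[, , 2] + t2[, , 3]) / 3
    t2 <- array(rep(gr, 3L), dim(t2))
  }
  if (stats::runif(1) < 0.5) t2 <- .box_blur3(t2)
  clamp01(t2)
}

# Deterministic tile -> encoder-input resize used at feature-extraction time.
.tile_to_input <- function(tile, in_px) {
  p <- dim(tile)[1]
  if (p == in_px) return(tile)
  if (p %% in_px == 0L) block_downsample(tile, p %/% in_px)
  else resize_bilinear(tile, in_px, in_px)
}
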