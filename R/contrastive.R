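#' Temperature-scaled cosine similarity
#'
#' \code{sim(z_i, z_j) = z_i' z_j / (tau * |z_i| * |z_j|)}.
#'
#' @param z_i,z_j Nonzero numeric vectors of equal length.
#' @param tau Positive temperature.
#' @return A scalar similarity.
#' @export
cosine_sim <- function(z_i, z_j, tau = 1) {
  if (tau <= 0) stop("tau must be positive")
  ni <- sqrt(sum(z_i^2)); nj <- sqrt(sum(z_j^2))
  if (ni == 0 || nj == 0) stop("cosine similarity is undefined for a zero vector")
  sum(z_i * z_j) / (tau * ni * nj)
}

#' Create a FIFO memory queue of cached negatives
#'
#' The queue stores K unit-norm key vectors in a ring buffer; new keys
#' overwrite the oldest.  It is initialized with seeded random unit vectors
#' so the contrastive loss is defined from the first step.
#'
#' @param K Queue capacity (number of cached negatives).
#' @param dz Key dimension.
#' @param seed Seed for the random initialization.
#' @return An object of class \code{memory_queue}.
#' @export
memory_queue <- function(K, dz, seed = 1L) {
  stopifnot(K >= 1, dz >= 1)
  set.seed(seed)
  buf <- matrix(stats::rnorm(K * dz), K, dz)
  buf <- buf / sqrt(rowSums(buf^2))
  structure(list(buffer = buf, K = as.integer(K), head = 1L, inserted = 0L),
            class = "memory_queue")
}

#' Enqueue keys into a memory queue
#'
#' @param queue A \code{\link{memory_queue}}.
#' @param keys Matrix of keys (rows); they are L2-normalized on insertion.
#' @return The updated queue.
#' @export
queue_push <- function(queue, keys) {
  stopifnot(inherits(queue, "memory_queue"))
  keys <- rbind(keys)
  keys <- keys / pmax(sqrt(rowSums(keys^2)), 1e-12)
  nb <- nrow(keys)
  pos <- ((queue$head - 1L + seq_len(nb) - 1L) %% queue$K) + 1L
  queue$buffer[pos, ] <- keys
  queue$head <- ((queue$head - 1L + nb) %% queue$K) + 1L
  queue$inserted <- queue$inserted + nb
  queue
}

.logsumexp <- function(x) { m <- max(x); m + log(sum(exp(x - m))) }

#' InfoNCE contrastive loss for one anchor
#'
#' \code{-log( exp(sim(z, z_pos)) / (exp(sim(z, z_pos)) + sum_k exp(sim(z, z_k))) )}
#' with the K queue entries as negatives and similarities from
#' \code{\link{cosine_sim}} at temperature \code{tau}.  The default
#' denominator includes the positive term (the bounded, standard
#' momentum-contrast form); \code{denominator = "literal"} sums only the K
#' negatives.
#'
#' @param z Anchor vector.
#' @param z_pos Positive key vector.
#' @param queue A non-empty \code{\link{memory_queue}}.
#' @param tau Positive temperature.
#' @param denominator \code{"inclusive"} (default) or \code{"literal"}.
#' @return The scalar loss.
#' @export
info_nce_loss <- function(z, z_pos, queue, tau = 0.07,
                          denominator = c("inclusive", "literal")) {
  denominator <- match.arg(denominator)
  if (tau <= 0) stop("tau must be positive")
  stopifnot(inherits(queue, "memory_queue"))
  pos <- cosine_sim(z, z_pos, tau)
  zn <- z / sqrt(sum(z^2))
  negs <- as.vector(queue$buffer %*% zn) / tau   # queue rows are unit norm
  if (denominator == "inclusive") .logsumexp(c(pos, negs)) - pos
  else .logsumexp(negs) - pos
}

# Batch InfoNCE on normalized embeddings.  Qn, Kn: n x dz unit-row matrices.
# Returns mean loss and the gradient wrt Qn (treating Kn and the queue as
# constants, as in momentum contrast).
.nce_batch <- function(Qn, Kn, buffer, tau, denominator = "inclusive") {
  n <- nrow(Qn)
  pos <- rowSums(Qn * Kn) / tau                   # n
  negs <- tcrossprod(Qn, buffer) / tau            # n x K
  logits <- cbind(pos, negs)
  m <- apply(logits, 1, max)
  ex <- exp(logits - m)
  if (denominator == "inclusive") {
    den <- rowSums(ex)
    loss <- mean(log(den) + m - pos)
    sm <- ex / den                                # softmax over (pos, negs)
    dlog <- sm; dlog[, 1] <- dlog[, 1] - 1        # d loss_i / d logits
  } else {
    den <- rowSums(ex[, -1, drop = FALSE])
    loss <- mean(log(den) + m - pos)
    sm <- ex[, -1, drop = FALSE] / den
    dlog <- cbind(-1, sm)
  }
  dlog <- dlog / n
  dQn <- (dlog[, 1] / tau) * Kn + (dlog[, -1, drop = FALSE] %*% buffer) / tau
  list(loss = loss, dQn = dQn)
}

#' Momentum (EMA) update of the key encoder
#'
#' Sets every key-encoder tensor to \code{m * key + (1 - m) * online} and,
#' when \code{keys} are supplied, enqueues them into the memory queue
#' (dequeuing the oldest).
#'
#' @param encoder A \code{\link{pretrain}} state (class \code{moco_encoder}).
#' @param m Momentum coefficient in \[0, 1).
#' @param keys Optional matrix of new key vectors to enqueue.
#' @return The updated encoder state.
#' @export
momentum_update <- function(encoder, m, keys = NULL) {
  stopifnot(inherits(encoder, "moco_encoder"))
  if (m < 0 || m >= 1) stop("momentum coefficient m must be in [0, 1)")
  for (nm in names(encoder$params))
    encoder$key_params[[nm]] <- m * encoder$key_params[[nm]] + (1 - m) * encoder$params[[nm]]
  if (!is.null(keys)) encoder$queue <- queue_push(encoder$queue, keys)
  encoder
}

# Collect tiles (as a list of [p,p,3] arrays) from one bag or a list of bags,
# with optional seeded per-slide and per-tile uniform subsampling.
.collect_tiles <- function(bags, slide_sample = 1, tile_sample = 1) {
  if (inherits(bags, "tile_bag")) bags <- list(bags)
  if (slide_sample < 1) {
    keep <- sort(sample.int(length(bags), max(1L, ceiling(slide_sample * length(bags)))))
    bags <- bags[keep]
  }
  tiles <- list()
  for (bag in bags) {
    n <- dim(bag$tiles)[1]
    if (n == 0L) next
    idx <- seq_len(n)
    if (tile_sample < 1)
      idx <- sort(sample.int(n, max(1L, ceiling(tile_sample * n))))
    for (i in idx) tiles[[length(tiles) + 1L]] <- bag$tiles[i, , , ]
  }
  tiles
}

#' Momentum-contrast pretraining of the tile encoder
#'
#' Self-supervised pretraining: each tile is augmented twice; the online
#' encoder embeds one view (query), an EMA "key" encoder embeds the other,
#' and the InfoNCE loss contrasts the positive pair against K cached
#' negatives from a FIFO memory queue.  Optimized with SGD
#' (lr 0.03, weight decay 1e-4, momentum 0.9 by default).  After training
#' the projection head is discarded for feature extraction:
#' \code{\link{embed_tiles}} returns backbone embeddings h.
#'
#' @param bags A \code{tile_bag} or list of them.
#' @param epochs,batch_size Training schedule.
#' @param lr,weight_decay,sgd_momentum SGD hyperparameters.
#' @param tau InfoNCE temperature.
#' @param queue_K Memory-queue capacity.
#' @param momentum_m EMA coefficient for the key encoder.
#' @param in_px,conv_channels,embed_dim,proj_dim Encoder architecture.
#' @param denominator InfoNCE denominator form (see \code{\link{info_nce_loss}}).
#' @param slide_sample,tile_sample Seeded uniform subsampling fractions
#'   (fraction of slides used, fraction of tiles per slide).
#' @param seed Seed controlling initialization, sampling and augmentation.
#' @return An object of class \code{moco_encoder} with the online and key
#'   parameters, queue, config, and a per-epoch training log.
#' @export
pretrain <- function(bags, epochs = 5L, batch_size = 64L, lr = 0.03,
                     weight_decay = 1e-4, sgd_momentum = 0.9, tau = 0.07,
                     queue_K = 256L, momentum_m = 0.999, in_px = 32L,
                     conv_channels = 8L, embed_dim = 32L, proj_dim = 16L,
                     denominator = c("inclusive", "literal"),
                     slide_sample = 1, tile_sample = 1, seed = 1L) {
  denominator <- match.arg(denominator)
  if (tau <= 0) stop("tau must be positive")
  cfg <- .encoder_config(in_px, conv_channels, embed_dim, proj_dim)
  set.seed(derive_seed(seed, 1L))
  tiles <- .collect_tiles(bags, slide_sample, tile_sample)
  if (length(tiles) < 2L) stop("pretraining requires at least 2 tiles")

  par <- .encoder_init(cfg, derive_seed(seed, 2L))
  key <- par
  queue <- memory_queue(queue_K, cfg$dz, derive_seed(seed, 3L))
  vel <- .zeros_like(par)
  idx <- .im2col_index(cfg$in_px)
  n_tiles <- length(tiles)
  log <- data.frame(epoch = integer(0), loss = numeric(0), lr = numeric(0))
  step <- 0L

  # queue burn-in: replace the random initialization with real key
  # embeddings so first-epoch losses are measured against genuine negatives
  set.seed(derive_seed(seed, 5L))
  burn <- sample.int(n_tiles, min(n_tiles, queue_K), replace = n_tiles < queue_K)
  for (b0 in seq(1L, length(burn), by = batch_size)) {
    bi <- burn[b0:min(b0 + batch_size - 1L, length(burn))]
    Xb <- array(0, c(length(bi), cfg$in_px, cfg$in_px, 3))
    for (j in seq_along(bi)) Xb[j, , , ] <- .augment_tile(tiles[[bi[j]]], cfg$in_px)
    queue <- queue_push(queue, .encoder_forward(key, cfg, Xb, idx, project = TRUE)$z)
  }

  set.seed(derive_seed(seed, 4L))
  for (ep in seq_len(epochs)) {
    perm <- sample.int(n_tiles)
    losses <- c()
    for (b0 in seq(1L, n_tiles, by = batch_size)) {
      bi <- perm[b0:min(b0 + batch_size - 1L, n_tiles)]
      nb <- length(bi)
      Xq <- array(0, c(nb, cfg$in_px, cfg$in_px, 3))
      Xk <- array(0, c(nb, cfg$in_px, cfg$in_px, 3))
      for (j in seq_len(nb)) {
        Xq[j, , , ] <- .augment_tile(tiles[[bi[j]]], cfg$in_px)
        Xk[j, , , ] <- .augment_tile(tiles[[bi[j]]], cfg$in_px)
      }
      fq <- .encoder_forward(par, cfg, Xq, idx, project = TRUE, keep_cache = TRUE)
      fk <- .encoder_forward(key, cfg, Xk, idx, project = TRUE, keep_cache = FALSE)
      nce <- .nce_batch(fq$z, fk$z, queue$buffer, tau, denominator)
      if (!is.finite(nce$loss))
        stop(sprintf("non-finite contrastive loss at epoch %d, step %d", ep, step))
      losses <- c(losses, nce$loss)
      grads <- .encoder_backward(par, cfg, fq$cache, dZ = nce$dQn)
      upd <- .sgd_step(par, grads, vel, lr, sgd_momentum, weight_decay)
      par <- upd$par; vel <- upd$vel
      for (nm in names(par)) key[[nm]] <- momentum_m * key[[nm]] + (1 - momentum_m) * par[[nm]]
      queue <- queue_push(queue, fk$z)
      step <- step + 1L
    }
    log <- rbind(log, data.frame(epoch = ep, loss = mean(losses), lr = lr))
  }
  structure(list(params = par, key_params = key, queue = queue, config = c(
    cfg, list(tau = tau, lr = lr, weight_decay = weight_decay,
              sgd_momentum = sgd_momentum, momentum_m = momentum_m,
              queue_K = queue_K, denominator = denominator, seed = seed,
              epochs = epochs, batch_size = batch_size)),
    log = log, steps = step), class = "moco_encoder")
}

#' @export
print.moco_encoder <- function(x, ...) {
  cat(sprintf(paste0("<moco_encoder> in %dpx, %d conv ch, h dim %d, z dim %d | ",
                     "tau %.3g, K %d | %d steps, final loss %.4f\n"),
              x$config$in_px, x$config$C, x$config$d, x$config$dz,
              x$config$tau, x$config$queue_K, x$steps,
              if (nrow(x$log)) x$log$loss[nrow(x$log)] else NA))
  invisible(x)
}

#' Embed a tile bag with a trained encoder
#'
#' Applies the backbone (projection head discarded) to every tile; tiles are
#' deterministically resized to the encoder input size.  Row order matches
#' bag order.
#'
#' @param bag A \code{tile_bag}.
#' @param encoder A \code{moco_encoder}.
#' @return An N x d matrix of embeddings with the bag's coordinates attached
#'   as attribute \code{"coords"}; an empty bag yields a 0 x d matrix.
#' @export
embed_tiles <- function(bag, encoder) {
  stopifnot(inherits(bag, "tile_bag"), inherits(encoder, "moco_encoder"))
  cfg <- encoder$config
  n <- dim(bag$tiles)[1]
  if (n == 0L) {
    out <- matrix(0, 0, cfg$d)
    attr(out, "coords") <- bag$coords
    return(out)
  }
  X <- array(0, c(n, cfg$in_px, cfg$in_px, 3))
  for (i in seq_len(n)) X[i, , , ] <- .tile_to_input(bag$tiles[i, , , ], cfg$in_px)
  idx <- .im2col_index(cfg$in_px)
  H <- .encoder_forward(encoder$params, cfg, X, idx, project = FALSE)$h
  attr(H, "coords") <- bag$coords
  H
}
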