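#' Initialize gated-attention parameters
#'
#' @param d Embedding dimension.
#' @param L Attention hidden dimension.
#' @param seed Seed for the random initialization.
#' @return List with matrices \code{V} (L x d), \code{U} (L x d) and vector
#'   \code{w} (length L).
#' @export
attention_params <- function(d, L = 128L, seed = 1L) {
  set.seed(seed)
  sc <- sqrt(1 / d)
  list(V = matrix(stats::rnorm(L * d, 0, sc), L, d),
       U = matrix(stats::rnorm(L * d, 0, sc), L, d),
       w = stats::rnorm(L, 0, sqrt(1 / L)))
}

# softmax with max-subtraction
.softmax <- function(e) { ex <- exp(e - max(e)); ex / sum(ex) }

#' Gated-attention pooling of tile embeddings
#'
#' Scores each tile with a gated two-branch network,
#' \code{e_i = w' (tanh(V h_i) * sigm(U h_i))}, converts scores to weights
#' by a numerically stabilized softmax, and returns the attention-weighted
#' average \code{S = sum_i a_i h_i} — an instance-level weighted average
#' pooling whose weights are learned.
#'
#' @param H N x d matrix of tile embeddings (N >= 1); an attached
#'   \code{"coords"} attribute is propagated.
#' @param params Attention parameters from \code{\link{attention_params}}.
#' @return An object of class \code{slide_feature}: \code{S} (length-d
#'   vector), \code{attention} (length-N, nonnegative, sums to 1),
#'   \code{scores} (raw e), and \code{coords}.
#' @export
gated_attention <- function(H, params) {
  coords <- attr(H, "coords")
  H <- rbind(H)
  if (nrow(H) == 0L) stop("empty bag: gated attention requires N >= 1 tiles")
  G <- tanh(params$V %*% t(H)) * stats::plogis(params$U %*% t(H))  # L x N
  e <- as.vector(crossprod(G, params$w))
  a <- .softmax(e)
  structure(list(S = as.vector(crossprod(H, a)), attention = a, scores = e,
                 coords = coords),
            class = "slide_feature")
}

#' @export
print.slide_feature <- function(x, ...) {
  cat(sprintf("<slide_feature> d = %d over %d tiles | attention range [%.4f, %.4f]\n",
              length(x$S), length(x$attention), min(x$attention), max(x$attention)))
  invisible(x)
}

#' Highest- and lowest-attention tiles
#'
#' @param sf A \code{\link{gated_attention}} result.
#' @param k Number of tiles per end (k <= N).
#' @return List with data.frames \code{top} and \code{bottom} (index,
#'   attention, and coordinates when available), ties broken by row-major
#'   tile order.
#' @export
attention_ranking <- function(sf, k) {
  stopifnot(inherits(sf, "slide_feature"))
  n <- length(sf$attention)
  if (k > n) stop("k exceeds the number of tiles")
  take <- function(ord) {
    idx <- ord[seq_len(k)]
    out <- data.frame(index = idx, attention = sf$attention[idx])
    if (!is.null(sf$coords) && nrow(sf$coords) == n) {
      out$x0 <- sf$coords[idx, 1]; out$y0 <- sf$coords[idx, 2]
    }
    out
  }
  list(top = take(order(-sf$attention, seq_len(n))),
       bottom = take(order(sf$attention, seq_len(n))))
}

# Backward pass through gated attention.
# Given dS (d), returns gradients for V, U, w and (optionally) for H.
.attention_backward <- function(H, params, sf, dS, de_extra = NULL, need_dH = FALSE) {
  N <- nrow(H); a <- sf$attention
  VH <- params$V %*% t(H); UH <- params$U %*% t(H)
  Tn <- tanh(VH); Sg <- stats::plogis(UH)
  da <- as.vector(H %*% dS)                       # dL/da_i
  # softmax backward: de = a * (da - sum(a * da))
  de <- a * (da - sum(a * da))
  if (!is.null(de_extra)) de <- de + de_extra
  # e_i = w' (Tn_i * Sg_i)
  G <- Tn * Sg                                    # L x N
  gW <- as.vector(G %*% de)                       # dL/dw
  # dL/d(Tn * Sg) column i = w * de_i
  M <- outer(params$w, de)                        # L x N
  dV <- (M * Sg * (1 - Tn^2)) %*% H               # L x d
  dU <- (M * Tn * Sg * (1 - Sg)) %*% H
  out <- list(V = dV, U = dU, w = gW)
  if (need_dH) {
    dH <- a %o% dS                                # from S = sum a_i h_i
    dE <- M * Sg * (1 - Tn^2)                     # L x N, through V branch
    dH <- dH + t(crossprod(params$V, dE))         # dh_i += V' dE[, i]
    dF <- M * Tn * Sg * (1 - Sg)
    dH <- dH + t(crossprod(params$U, dF))
    out$dH <- dH
  }
  out
}
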