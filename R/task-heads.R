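#' Linear classification head with softmax
#'
#' @param S Slide feature vector (length d).
#' @param params List with \code{W} (d x 2) and \code{b} (length 2).
#' @return Probability vector over the two classes (sums to 1).
#' @export
classify_head <- function(S, params) {
  logits <- as.vector(crossprod(params$W, S)) + params$b
  if (any(!is.finite(logits))) stop("non-finite logits in classification head")
  p <- .softmax(logits)
  names(p) <- names(params$b)
  p
}

#' Mean squared error over a protein panel
#'
#' \code{(1/N) sum_i (y_i - yhat_i)^2} with N the number of proteins.
#'
#' @param y Measured levels.
#' @param y_hat Predicted levels (same length).
#' @return Scalar loss.
#' @export
mse_loss <- function(y, y_hat) {
  if (length(y) != length(y_hat)) stop("y and y_hat must have equal length")
  mean((y - y_hat)^2)
}

.head_init <- function(task, d, n_outputs, hidden, seed) {
  set.seed(seed)
  sc <- sqrt(1 / d)
  if (task == "protein") {
    list(W1 = matrix(stats::rnorm(d * hidden, 0, sc), d, hidden), b1 = numeric(hidden),
         W2 = matrix(stats::rnorm(hidden * n_outputs, 0, sqrt(1 / hidden)),
                     hidden, n_outputs), b2 = numeric(n_outputs))
  } else {
    list(W = matrix(stats::rnorm(d * 2L, 0, sc), d, 2L), b = numeric(2L))
  }
}

# Forward + loss + gradients for one slide.  Returns loss, head grads, dS.
.head_step <- function(task, head, S, target) {
  if (task == "protein") {
    a1 <- as.vector(crossprod(head$W1, S)) + head$b1
    r <- pmax(a1, 0)
    yhat <- as.vector(crossprod(head$W2, r)) + head$b2
    K <- length(target)
    loss <- mean((target - yhat)^2)
    dy <- 2 * (yhat - target) / K
    dr <- as.vector(head$W2 %*% dy)
    da1 <- dr * (a1 > 0)
    list(loss = loss, pred = yhat,
         grads = list(W1 = S %o% da1, b1 = da1, W2 = r %o% dy, b2 = dy),
         dS = as.vector(head$W1 %*% da1))
  } else {
    logits <- as.vector(crossprod(head$W, S)) + head$b
    p <- .softmax(logits)
    lab <- target + 1L                     # 0/1 -> column index
    loss <- -log(max(p[lab], 1e-12))
    dlog <- p; dlog[lab] <- dlog[lab] - 1
    list(loss = loss, pred = p[2L],
         grads = list(W = S %o% dlog, b = dlog),
         dS = as.vector(head$W %*% dlog))
  }
}

#' Compute per-slide tile-embedding matrices for a cohort
#'
#' Reads each slide in the manifest, segments tissue, tessellates, optionally
#' color-normalizes, and embeds the tiles with the trained encoder.
#'
#' @param manifest A \code{\link{make_cohort}} manifest (or any data.frame
#'   with \code{slide_id} and \code{path} columns).
#' @param encoder A \code{\link{pretrain}} state.
#' @param tile_px,min_tissue_frac,downsample Tiling settings.
#' @param normalize Apply Reinhard color normalization to each bag.
#' @return Named list (by slide_id) of N x d embedding matrices with tile
#'   coordinates attached.
#' @export
cohort_features <- function(manifest, encoder, tile_px = 256L,
                            min_tissue_frac = 0.5, downsample = 8L,
                            normalize = FALSE) {
  out <- vector("list", nrow(manifest))
  names(out) <- manifest$slide_id
  for (i in seq_len(nrow(manifest))) {
    sl <- read_slide(manifest$path[i], slide_id = manifest$slide_id[i])
    bag <- tessellate(sl, segment_tissue(sl, downsample), tile_px, min_tissue_frac)
    if (normalize) bag <- normalize_color(bag)
    out[[i]] <- embed_tiles(bag, encoder)
  }
  out
}

#' Tile bags for a cohort (needed for encoder fine-tuning)
#'
#' @inheritParams cohort_features
#' @return Named list of \code{tile_bag} objects.
#' @export
cohort_bags <- function(manifest, tile_px = 256L, min_tissue_frac = 0.5,
                        downsample = 8L, normalize = FALSE) {
  out <- vector("list", nrow(manifest))
  names(out) <- manifest$slide_id
  for (i in seq_len(nrow(manifest))) {
    sl <- read_slide(manifest$path[i], slide_id = manifest$slide_id[i])
    bag <- tessellate(sl, segment_tissue(sl, downsample), tile_px, min_tissue_frac)
    if (normalize) bag <- normalize_color(bag)
    out[[i]] <- bag
  }
  out
}

.task_labels <- function(manifest, task, protein_cols) {
  switch(task,
    diagnosis = list(y = as.integer(manifest$tumor_flag), used = "tumor_flag"),
    response = list(y = as.integer(manifest$responder), used = "responder"),
    protein = list(y = as.matrix(manifest[, protein_cols, drop = FALSE]),
                   used = protein_cols))
}

#' Fit an attention-MIL task model
#'
#' Trains the gated-attention pooling together with a slide-level head —
#' tumor/normal diagnosis (linear + softmax, cross-entropy), multi-task
#' protein regression (single hidden layer, MSE averaged over proteins), or
#' binary drug-response classification — using only slide-level labels.
#' Optimized with Adam on per-slide updates; early-stops on validation-split
#' loss with the given patience and restores the best parameters.  With
#' \code{freeze_encoder = FALSE} the gradient flows through the attention
#' pooling into the tile encoder, which is then updated jointly
#' (tile bags must be supplied via \code{bags}).
#'
#' The function reads only the label columns the task needs (recorded in
#' \code{$labels_used}); in particular the protein task never touches the
#' responder column, which is what makes HER2-proxy response prediction
#' label-isolated.
#'
#' @param manifest Cohort manifest with \code{split} column.
#' @param encoder A \code{\link{pretrain}} state.
#' @param task \code{"diagnosis"}, \code{"protein"} or \code{"response"}.
#' @param features Optional precomputed \code{\link{cohort_features}} list
#'   (computed on the fly otherwise).
#' @param bags Tile bags (named by slide_id), required when fine-tuning.
#' @param L Attention hidden dimension.
#' @param hidden Hidden width of the protein head.
#' @param lr Adam learning rate.
#' @param epochs,patience Schedule and early-stopping patience.
#' @param freeze_encoder Keep the encoder fixed (default) or fine-tune it.
#' @param seed Seed for initialization and slide order.
#' @param tile_px,min_tissue_frac,downsample Passed to
#'   \code{\link{cohort_features}} when features are computed here.
#' @return An object of class \code{mil_model}.
#' @export
mil_fit <- function(manifest, encoder, task = c("diagnosis", "protein", "response"),
                    features = NULL, bags = NULL, L = 128L, hidden = 64L,
                    lr = 1e-4, epochs = 200L, patience = 40L,
                    freeze_encoder = TRUE, seed = 1L,
                    tile_px = 256L, min_tissue_frac = 0.5, downsample = 8L) {
  task <- match.arg(task)
  protein_cols <- protein_columns(manifest)
  lab <- .task_labels(manifest, task, protein_cols)
  if (task != "protein" && length(unique(lab$y)) < 2L)
    stop("classification training requires both classes among the labels")
  if (!freeze_encoder && is.null(bags))
    stop("encoder fine-tuning requires tile bags; supply 'bags' (see cohort_bags)")
  if (is.null(features)) {
    if (!is.null(bags)) features <- lapply(bags, embed_tiles, encoder = encoder)
    else features <- cohort_features(manifest, encoder, tile_px, min_tissue_frac, downsample)
  }
  features <- features[manifest$slide_id]

  # standardize embedding dimensions over training-split tiles: encoder
  # outputs are strongly correlated (shared brightness direction), and the
  # heads are badly conditioned without this
  tr0 <- which(manifest$split == "train")
  if (!length(tr0)) stop("manifest has no training split")
  Htr <- do.call(rbind, features[tr0])
  scale_mu <- colMeans(Htr)
  scale_sd <- apply(Htr, 2, stats::sd)
  scale_sd[!is.finite(scale_sd) | scale_sd < 1e-8] <- 1
  features <- lapply(features, function(h) {
    hs <- sweep(sweep(h, 2, scale_mu), 2, scale_sd, "/")
    attr(hs, "coords") <- attr(h, "coords")
    hs
  })

  d <- encoder$config$d
  n_out <- if (task == "protein") length(protein_cols) else 2L
  att <- attention_params(d, L, derive_seed(seed, 11L))
  head <- .head_init(task, d, n_out, hidden, derive_seed(seed, 12L))
  cfg <- encoder$config
  idx <- if (!freeze_encoder) .im2col_index(cfg$in_px) else NULL
  enc_par <- encoder$params

  # pre-resized encoder inputs per slide, only needed when fine-tuning
  inputs <- NULL
  if (!freeze_encoder) {
    inputs <- lapply(bags[manifest$slide_id], function(bag) {
      n <- dim(bag$tiles)[1]
      X <- array(0, c(n, cfg$in_px, cfg$in_px, 3))
      for (i in seq_len(n)) X[i, , , ] <- .tile_to_input(bag$tiles[i, , , ], cfg$in_px)
      X
    })
  }

  tr <- tr0
  va <- which(manifest$split == "val")

  slide_loss <- function(i, att_, head_, feats) {
    sf <- gated_attention(feats[[i]], att_)
    tgt <- if (task == "protein") lab$y[i, ] else lab$y[i]
    .head_step(task, head_, sf$S, tgt)$loss
  }

  adam <- list(t = 0L,
               m = .zeros_like(c(att, head)), v = .zeros_like(c(att, head)))
  adam_enc <- if (!freeze_encoder)
    list(t = 0L, m = .zeros_like(enc_par), v = .zeros_like(enc_par)) else NULL

  best <- list(loss = Inf, att = att, head = head, enc = enc_par, epoch = 0L)
  wait <- 0L
  log <- data.frame(epoch = integer(0), train_loss = numeric(0), val_loss = numeric(0))
  set.seed(derive_seed(seed, 13L))

  for (ep in seq_len(epochs)) {
    tr_losses <- numeric(0)
    for (i in sample(tr)) {
      H <- features[[i]]
      if (nrow(H) == 0L) next
      sf <- gated_attention(H, att)
      tgt <- if (task == "protein") lab$y[i, ] else lab$y[i]
      hs <- .head_step(task, head, sf$S, tgt)
      tr_losses <- c(tr_losses, hs$loss)
      ab <- .attention_backward(H, att, sf, hs$dS, need_dH = !freeze_encoder)
      grads <- c(ab[c("V", "U", "w")], hs$grads)
      upd <- .adam_step(c(att, head), grads, adam, lr)
      adam <- upd$st
      att <- upd$par[c("V", "U", "w")]
      head <- upd$par[setdiff(names(upd$par), c("V", "U", "w"))]
      if (!freeze_encoder) {
        fe <- .encoder_forward(enc_par, cfg, inputs[[i]], idx,
                               project = FALSE, keep_cache = TRUE)
        # features seen by the attention/head are (h - mu) / sd
        eg <- .encoder_backward(enc_par, cfg, fe$cache,
                                dH = sweep(ab$dH, 2, scale_sd, "/"))
        eg <- eg[setdiff(names(eg), c("Wp1", "bp1", "Wp2", "bp2"))]
        updE <- .adam_step(enc_par, eg, adam_enc, lr)
        enc_par <- updE$par; adam_enc <- updE$st
      }
    }
    if (!freeze_encoder) {
      for (i in seq_along(features)) {
        h <- .encoder_forward(enc_par, cfg, inputs[[i]], idx, project = FALSE)$h
        h <- sweep(sweep(h, 2, scale_mu), 2, scale_sd, "/")
        attr(h, "coords") <- attr(features[[i]], "coords")
        features[[i]] <- h
      }
    }
    monitor <- if (length(va)) va else tr
    vloss <- mean(vapply(monitor, slide_loss, 0, att_ = att, head_ = head,
                         feats = features))
    log <- rbind(log, data.frame(epoch = ep, train_loss = mean(tr_losses),
                                 val_loss = vloss))
    if (vloss < best$loss - 1e-9) {
      best <- list(loss = vloss, att = att, head = head, enc = enc_par, epoch = ep)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= patience) break
    }
  }

  enc_out <- encoder
  enc_out$params <- best$enc
  structure(list(task = task, att = best$att, head = best$head,
                 scale = list(mu = scale_mu, sd = scale_sd),
                 encoder = enc_out, freeze_encoder = freeze_encoder,
                 protein_names = if (task == "protein") protein_cols else NULL,
                 labels_used = lab$used,
                 config = list(L = L, hidden = hidden, lr = lr, epochs = epochs,
                               patience = patience, seed = seed),
                 log = log, best_epoch = best$epoch, val_loss = best$loss),
            class = "mil_model")
}

#' @export
print.mil_model <- function(x, ...) {
  cat(sprintf("<mil_model> task '%s' | L = %d | %s encoder | best epoch %d (val loss %.4f)\n",
              x$task, x$config$L,
              if (x$freeze_encoder) "frozen" else "fine-tuned",
              x$best_epoch, x$val_loss))
  invisible(x)
}

#' @export
summary.mil_model <- function(object, ...) {
  cat(sprintf("Attention-MIL model, task '%s'\n", object$task))
  cat(sprintf("  labels used during fitting: %s\n",
              paste(utils::head(object$labels_used, 5), collapse = ", ")))
  if (length(object$labels_used) > 5) cat("  ...\n")
  cat(sprintf("  epochs run: %d, best: %d, best monitored loss: %.5f\n",
              nrow(object$log), object$best_epoch, object$val_loss))
  invisible(object)
}

#' Predict from a fitted attention-MIL model
#'
#' @param object A \code{\link{mil_fit}} model.
#' @param features Named list of slide embedding matrices (e.g. from
#'   \code{\link{cohort_features}} with the model's encoder).
#' @param type \code{"response"} for slide-level predictions (probability of
#'   the positive class, or a slide x protein matrix), or
#'   \code{"attention"} for the per-slide \code{slide_feature} objects.
#' @param ... Unused.
#' @return For \code{type = "response"}: a data.frame (classification) or a
#'   matrix with protein columns (regression).  For \code{"attention"}: a
#'   named list of \code{slide_feature} objects.
#' @export
predict.mil_model <- function(object, features, type = c("response", "attention"), ...) {
  type <- match.arg(type)
  features <- lapply(features, function(h) {
    hs <- sweep(sweep(h, 2, object$scale$mu), 2, object$scale$sd, "/")
    attr(hs, "coords") <- attr(h, "coords")
    hs
  })
  sfs <- lapply(features, gated_attention, params = object$att)
  if (type == "attention") return(sfs)
  if (object$task == "protein") {
    out <- t(vapply(sfs, function(sf) {
      r <- pmax(as.vector(crossprod(object$head$W1, sf$S)) + object$head$b1, 0)
      as.vector(crossprod(object$head$W2, r)) + object$head$b2
    }, numeric(length(object$protein_names))))
    colnames(out) <- object$protein_names
    rownames(out) <- names(features)
    out
  } else {
    p <- vapply(sfs, function(sf) classify_head(sf$S, object$head)[2L], 0)
    data.frame(slide_id = names(features), prob = unname(p))
  }
}

#' Predict drug response from a protein-trained model via the HER2 proxy
#'
#' The response score of a case is its predicted HER2-like protein level
#' from a model fine-tuned on protein labels only: treatment-outcome labels
#' are never consumed.  With multiple slides per patient, slide scores are
#' averaged per patient.  Downstream evaluation compares the (appropriately
#' signed) score to responder labels with ROC/AUC; a hard call, when needed,
#' thresholds at the training-split median score.
#'
#' @param manifest Cohort manifest (provides patient/slide mapping).
#' @param protein_model A \code{\link{mil_fit}} model with
#'   \code{task = "protein"}.
#' @param her2_name Name of the HER2-like protein among the model outputs.
#' @param features Named list of slide embeddings for the slides to score.
#' @return data.frame with patient_id, score (predicted HER2-like level) and
#'   call (score below training-median = predicted responder in the
#'   synthetic convention); attribute \code{"threshold"} carries the cut.
#' @export
predict_response_via_her2 <- function(manifest, protein_model, her2_name, features) {
  stopifnot(inherits(protein_model, "mil_model"))
  if (protein_model$task != "protein")
    stop("predict_response_via_her2 requires a protein-task model")
  if (!her2_name %in% protein_model$protein_names)
    stop("protein '", her2_name, "' is not among the model outputs")
  pred <- predict(protein_model, features)[, her2_name]
  df <- data.frame(slide_id = names(features), score = unname(pred))
  df <- merge(df, manifest[, c("slide_id", "patient_id", "split")], by = "slide_id")
  agg <- stats::aggregate(score ~ patient_id, data = df, FUN = mean)
  thr_scores <- df$score[df$split == "train"]
  thr <- if (length(thr_scores)) stats::median(thr_scores) else stats::median(df$score)
  agg$call <- agg$score < thr
  attr(agg, "threshold") <- thr
  agg
}
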