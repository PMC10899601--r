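#' Resolve a pipeline run configuration
#'
#' Builds the flat key = value configuration that drives
#' \code{\link{run_pipeline}}: package defaults, overridden by an optional
#' config file (one \code{key = value} per line, \code{#} comments),
#' overridden by \code{...}.  Every run writes a frozen copy of the resolved
#' configuration into its output directory so deterministic stages can be
#' reproduced bit-for-bit.
#'
#' @param file Optional config file path.
#' @param ... Named overrides.
#' @return A named list of class \code{run_config}.
#' @export
run_config <- function(file = NULL, ...) {
  cfg <- list(
    out_dir = file.path(tempdir(), "wsimil_run"),
    seed = 1, n_slides = 20, slide_px = 256, tile_px = 32,
    tissue_lo = 0.35, tissue_hi = 0.6, tumor_lo = 0.2, tumor_hi = 0.6,
    tumor_prevalence = 0.6, n_proteins = 12, n_signal_proteins = 4,
    noise_sd = 0.1, censoring_rate = 0.3, contrast = 1,
    min_tissue_frac = 0.5, downsample = 8,
    tau = 0.07, queue_K = 256, momentum_m = 0.999, epochs_pretrain = 3,
    batch_size = 64, lr_pretrain = 0.03, weight_decay = 1e-4,
    sgd_momentum = 0.9, in_px = 32, conv_channels = 8, embed_dim = 32,
    proj_dim = 16, slide_sample = 1, tile_sample = 1,
    task = "diagnosis", L = 128, hidden = 64, lr_head = 1e-4,
    epochs_head = 150, patience = 15, freeze_encoder = TRUE,
    cv_k = 5, heat_alpha = 0.5, heat_downsample = 32)
  if (!is.null(file)) {
    if (!file.exists(file)) stop("config file not found: ", file)
    for (ln in readLines(file)) {
      ln <- sub("#.*$", "", ln)
      if (!grepl("=", ln)) next
      key <- trimws(sub("=.*$", "", ln))
      val <- trimws(sub("^[^=]*=", "", ln))
      num <- suppressWarnings(as.numeric(val))
      if (val %in% c("TRUE", "FALSE", "true", "false"))
        val <- as.logical(toupper(val))
      else if (!is.na(num)) val <- num
      cfg[[key]] <- val
    }
  }
  dots <- list(...)
  for (nm in names(dots)) cfg[[nm]] <- dots[[nm]]
  class(cfg) <- "run_config"
  cfg
}

.cfg_write <- function(cfg, path) {
  lines <- vapply(names(cfg), function(nm) {
    v <- cfg[[nm]]
    sprintf("%s = %s", nm, if (is.character(v)) v else format(v, digits = 15))
  }, "")
  writeLines(lines, path)
}

.json_escape <- function(s) gsub('"', '\\\\"', gsub("\\\\", "\\\\\\\\", s))

.log_line <- function(log_path, stage, event, detail = "", hash = "") {
  line <- sprintf('{"ts":"%s","stage":"%s","event":"%s","detail":"%s","hash":"%s"}',
                  format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), stage, event,
                  .json_escape(detail), hash)
  cat(line, "\n", sep = "", file = log_path, append = TRUE)
}

.need_artifact <- function(path, producer, stage) {
  if (!file.exists(path))
    stop(sprintf("stage '%s' needs '%s'; run stage '%s' first", stage,
                 basename(path), producer), call. = FALSE)
}

.pipe_paths <- function(cfg) {
  o <- cfg$out_dir
  list(out = o,
       manifest = file.path(o, "cohort", "manifest.csv"),
       cohort_meta = file.path(o, "cohort", "cohort_meta.rds"),
       bags = file.path(o, "tiles", "bags.rds"),
       tiles_index = file.path(o, "tiles", "tiles_index.csv"),
       encoder = file.path(o, "pretrain", "encoder.rds"),
       pretrain_log = file.path(o, "pretrain", "log.csv"),
       model = file.path(o, "train", sprintf("model_%s.rds", cfg$task)),
       train_log = file.path(o, "train", sprintf("log_%s.csv", cfg$task)),
       predictions = file.path(o, "predict", sprintf("predictions_%s.csv", cfg$task)),
       heatmap_dir = file.path(o, "heatmaps"),
       metrics = file.path(o, "evaluate", sprintf("metrics_%s.csv", cfg$task)),
       log = file.path(o, "pipeline_log.jsonl"))
}

.read_manifest <- function(pp) {
  meta <- readRDS(pp$cohort_meta)
  m <- utils::read.csv(pp$manifest, check.names = FALSE,
                       colClasses = c(slide_id = "character", patient_id = "character"))
  structure(m, class = c("cohort_manifest", "data.frame"),
            params = meta$params, her2_name = meta$her2_name)
}

#' Run pipeline stages
#'
#' Orchestrates the four-step flow — slide preprocessing, contrastive
#' pretraining, weakly-supervised fine-tuning on slide-level labels, and
#' attentive aggregation for downstream tasks — over a synthetic cohort.
#' Stages: \code{synthesize}, \code{tile}, \code{pretrain}, \code{train},
#' \code{predict}, \code{heatmap}, \code{evaluate}, or \code{all}.  Each
#' stage checks for its upstream artifacts and fails naming the producing
#' stage; runs append a structured line-JSON log with artifact hashes and
#' write a frozen copy of the resolved config.
#'
#' @param stage Stage name (or \code{"all"}).
#' @param config A \code{\link{run_config}} list.
#' @return Invisibly, the named list of artifact paths.
#' @export
run_pipeline <- function(stage = c("all", "synthesize", "tile", "pretrain",
                                   "train", "predict", "heatmap", "evaluate"),
                         config = run_config()) {
  stage <- match.arg(stage)
  cfg <- config
  pp <- .pipe_paths(cfg)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  .cfg_write(cfg, file.path(cfg$out_dir, "run_config_resolved.cfg"))
  stages <- if (stage == "all")
    c("synthesize", "tile", "pretrain", "train", "predict", "heatmap", "evaluate")
  else stage
  for (s in stages) .run_stage(s, cfg, pp)
  invisible(pp)
}

.run_stage <- function(stage, cfg, pp) {
  .log_line(pp$log, stage, "start", detail = sprintf("seed=%d", as.integer(cfg$seed)))
  switch(stage,
    synthesize = {
      params <- synthesis_params(
        slide_px = cfg$slide_px, tile_px = cfg$tile_px,
        tissue_fraction_range = c(cfg$tissue_lo, cfg$tissue_hi),
        tumor_fraction_range = c(cfg$tumor_lo, cfg$tumor_hi),
        tumor_prevalence = cfg$tumor_prevalence,
        n_proteins = cfg$n_proteins, n_signal_proteins = cfg$n_signal_proteins,
        noise_sd = cfg$noise_sd, censoring_rate = cfg$censoring_rate,
        contrast = cfg$contrast, seed = cfg$seed)
      man <- make_cohort(params, cfg$n_slides, dirname(pp$manifest))
      saveRDS(list(params = params, her2_name = attr(man, "her2_name")),
              pp$cohort_meta)
      .log_line(pp$log, stage, "done", detail = sprintf("%d slides", nrow(man)),
                hash = unname(tools::md5sum(pp$manifest)))
    },
    tile = {
      .need_artifact(pp$manifest, "synthesize", stage)
      man <- .read_manifest(pp)
      dir.create(dirname(pp$bags), recursive = TRUE, showWarnings = FALSE)
      bags <- cohort_bags(man, tile_px = cfg$tile_px,
                          min_tissue_frac = cfg$min_tissue_frac,
                          downsample = cfg$downsample)
      saveRDS(bags, pp$bags)
      idx <- do.call(rbind, lapply(bags, function(b) if (nrow(b$coords))
        data.frame(slide_id = b$slide_id, x0 = b$coords[, 1], y0 = b$coords[, 2],
                   magnification = b$magnification, tissue_frac = b$tissue_frac)))
      utils::write.csv(idx, pp$tiles_index, row.names = FALSE)
      .log_line(pp$log, stage, "done", detail = sprintf("%d tiles", nrow(idx)),
                hash = unname(tools::md5sum(pp$tiles_index)))
    },
    pretrain = {
      .need_artifact(pp$bags, "tile", stage)
      bags <- readRDS(pp$bags)
      enc <- pretrain(bags, epochs = cfg$epochs_pretrain, batch_size = cfg$batch_size,
                      lr = cfg$lr_pretrain, weight_decay = cfg$weight_decay,
                      sgd_momentum = cfg$sgd_momentum, tau = cfg$tau,
                      queue_K = cfg$queue_K, momentum_m = cfg$momentum_m,
                      in_px = cfg$in_px, conv_channels = cfg$conv_channels,
                      embed_dim = cfg$embed_dim, proj_dim = cfg$proj_dim,
                      slide_sample = cfg$slide_sample, tile_sample = cfg$tile_sample,
                      seed = cfg$seed)
      dir.create(dirname(pp$encoder), recursive = TRUE, showWarnings = FALSE)
      saveRDS(enc, pp$encoder)
      utils::write.csv(enc$log, pp$pretrain_log, row.names = FALSE)
      .log_line(pp$log, stage, "done",
                detail = sprintf("final loss %.4f", enc$log$loss[nrow(enc$log)]),
                hash = unname(tools::md5sum(pp$pretrain_log)))
    },
    train = {
      .need_artifact(pp$encoder, "pretrain", stage)
      .need_artifact(pp$bags, "tile", stage)
      enc <- readRDS(pp$encoder)
      bags <- readRDS(pp$bags)
      man <- .read_manifest(pp)
      task <- if (cfg$task == "response-proxy") "protein" else cfg$task
      model <- mil_fit(man, enc, task = task, bags = bags, L = cfg$L,
                       hidden = cfg$hidden, lr = cfg$lr_head,
                       epochs = cfg$epochs_head, patience = cfg$patience,
                       freeze_encoder = cfg$freeze_encoder, seed = cfg$seed)
      dir.create(dirname(pp$model), recursive = TRUE, showWarnings = FALSE)
      saveRDS(model, pp$model)
      utils::write.csv(model$log, pp$train_log, row.names = FALSE)
      .log_line(pp$log, stage, "done",
                detail = sprintf("best epoch %d", model$best_epoch),
                hash = unname(tools::md5sum(pp$train_log)))
    },
    predict = {
      .need_artifact(pp$model, "train", stage)
      .need_artifact(pp$bags, "tile", stage)
      model <- readRDS(pp$model)
      bags <- readRDS(pp$bags)
      man <- .read_manifest(pp)
      feats <- lapply(bags, embed_tiles, encoder = model$encoder)
      dir.create(dirname(pp$predictions), recursive = TRUE, showWarnings = FALSE)
      if (cfg$task == "response-proxy") {
        her2 <- readRDS(pp$cohort_meta)$her2_name
        sc <- predict_response_via_her2(man, model, her2, feats)
        utils::write.csv(sc, pp$predictions, row.names = FALSE)
      } else if (model$task == "protein") {
        pr <- predict(model, feats)
        out <- data.frame(slide_id = rownames(pr), pr, check.names = FALSE)
        utils::write.csv(out, pp$predictions, row.names = FALSE)
      } else {
        utils::write.csv(predict(model, feats), pp$predictions, row.names = FALSE)
      }
      .log_line(pp$log, stage, "done",
                hash = unname(tools::md5sum(pp$predictions)))
    },
    heatmap = {
      .need_artifact(pp$model, "train", stage)
      .need_artifact(pp$bags, "tile", stage)
      model <- readRDS(pp$model)
      bags <- readRDS(pp$bags)
      man <- .read_manifest(pp)
      dir.create(pp$heatmap_dir, recursive = TRUE, showWarnings = FALSE)
      test_ids <- man$slide_id[man$split == "test"]
      if (!length(test_ids)) test_ids <- man$slide_id
      for (sid in test_ids) {
        bag <- bags[[sid]]
        if (is.null(bag) || nrow(bag$coords) == 0L) next
        H <- embed_tiles(bag, model$encoder)
        sf <- predict(model, stats::setNames(list(H), sid), type = "attention")[[1]]
        sl <- read_slide(man$path[man$slide_id == sid], slide_id = sid)
        hm <- deconvolve(sf, c(sl$height_px, sl$width_px), bag$tile_px,
                         cfg$heat_downsample)
        export_overlay(hm, sl, file.path(pp$heatmap_dir, paste0(sid, ".png")),
                       alpha = cfg$heat_alpha)
      }
      .log_line(pp$log, stage, "done", detail = sprintf("%d maps", length(test_ids)))
    },
    evaluate = {
      .need_artifact(pp$predictions, "predict", stage)
      man <- .read_manifest(pp)
      pred <- utils::read.csv(pp$predictions, check.names = FALSE)
      dir.create(dirname(pp$metrics), recursive = TRUE, showWarnings = FALSE)
      test <- man[man$split == "test", ]
      metrics <- if (cfg$task == "diagnosis") {
        m <- merge(test[, c("slide_id", "tumor_flag")], pred, by = "slide_id")
        cm <- confusion_and_accuracy(m$prob > 0.5, m$tumor_flag)
        data.frame(metric = c("accuracy", "auc"),
                   value = c(cm$accuracy, roc_auc(m$prob, m$tumor_flag)))
      } else if (cfg$task == "response-proxy") {
        m <- merge(unique(man[, c("patient_id", "responder")]), pred,
                   by = "patient_id")
        data.frame(metric = "response_auc",
                   value = roc_auc(-m$score, m$responder))
      } else {
        prots <- protein_columns(man)
        m <- merge(test[, c("slide_id", prots)], pred, by = "slide_id",
                   suffixes = c("_true", "_pred"))
        res <- lapply(prots, function(pn)
          pearson(m[[paste0(pn, "_true")]], m[[paste0(pn, "_pred")]]))
        r <- vapply(res, `[[`, 0, "r"); p <- vapply(res, `[[`, 0, "p")
        adj <- bh_adjust(p)
        data.frame(metric = c(paste0("r_", prots), "mean_r", "n_significant"),
                   value = c(r, mean(r), sum(adj$reject)))
      }
      utils::write.csv(metrics, pp$metrics, row.names = FALSE)
      .log_line(pp$log, stage, "done", hash = unname(tools::md5sum(pp$metrics)))
    })
  invisible(NULL)
}
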