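#' Parameters for synthetic slide-cohort generation
#'
#' Bundles every knob of the synthetic whole-slide generator into a validated
#' parameter object.  The generator emulates the statistical structure a
#' weakly-supervised pathology pipeline assumes: each slide carries a smooth
#' tissue blob on a pale background, tumor-bearing slides embed subregions
#' with a visually distinct texture (denser dark nuclei-like speckle and a
#' hue shift), a subset of "signal" proteins is linearly coupled to the tumor
#' fraction, survival times follow an exponential proportional-hazards model
#' on latent slide features, and the drug-responder flag is a median split on
#' one designated HER2-like protein.
#'
#' @param slide_px Side of the square slide raster in pixels.
#' @param tile_px Tile side in pixels used downstream (default 256); slides
#'   must satisfy \code{slide_px >= 2 * tile_px}.
#' @param tissue_fraction_range Interval in \[0,1\]: the fraction of slide
#'   pixels covered by tissue is drawn uniformly from it.
#' @param tumor_fraction_range Interval in \[0,1\]: for tumor-bearing slides
#'   the target fraction of tissue pixels that are tumor is drawn from it.
#' @param tumor_prevalence Probability that a slide is tumor-bearing at all;
#'   remaining slides get an empty tumor mask and \code{tumor_flag = FALSE}.
#' @param n_proteins Size of the protein panel.
#' @param n_signal_proteins Number of leading panel members coupled to tumor
#'   fraction; the rest are pure noise.
#' @param signal_alpha Per-protein slopes for the signal proteins
#'   (\code{p_j = alpha_j * tumor_fraction + eps}).  Default: evenly spaced
#'   on \[0.8, 1.2\].
#' @param noise_sd Gaussian noise sd added to signal-protein levels.
#' @param noise_protein_sd Standard deviation of the pure-noise proteins.
#'   RPPA-style panels are normalized so proteins share comparable scales;
#'   the default matches the typical dispersion of the signal proteins.
#' @param cox_coefficients True log-hazard coefficients on the latent slide
#'   features (tumor fraction, mean nuclear-speckle density in tissue).
#' @param censoring_rate Expected fraction of censored survival records, via
#'   an independent per-subject exponential censoring time.
#' @param contrast Difficulty knob in (0, 1]: scales how far the tumor
#'   texture (hue shift and speckle density) departs from normal tissue.
#' @param seed Master seed; identical parameters reproduce the cohort
#'   bit-for-bit.
#' @return An object of class \code{synthesis_params}.
#' @export
synthesis_params <- function(slide_px = 512L, tile_px = 256L,
                             tissue_fraction_range = c(0.35, 0.6),
                             tumor_fraction_range = c(0.2, 0.6),
                             tumor_prevalence = 0.6,
                             n_proteins = 12L, n_signal_proteins = 4L,
                             signal_alpha = NULL,
                             noise_sd = 0.1, noise_protein_sd = 0.25,
                             cox_coefficients = c(3, 1),
                             censoring_rate = 0.3,
                             contrast = 1,
                             seed = 1L) {
  chk_range <- function(r, nm) {
    if (length(r) != 2L || any(!is.finite(r)) || r[1] > r[2] || r[1] < 0 || r[2] > 1)
      stop(sprintf("'%s' must be a non-empty interval within [0, 1]", nm))
  }
  chk_range(tissue_fraction_range, "tissue_fraction_range")
  chk_range(tumor_fraction_range, "tumor_fraction_range")
  if (n_signal_proteins > n_proteins)
    stop("n_signal_proteins must not exceed n_proteins")
  if (censoring_rate < 0 || censoring_rate >= 1)
    stop("censoring_rate must be in [0, 1)")
  if (tumor_prevalence < 0 || tumor_prevalence > 1)
    stop("tumor_prevalence must be in [0, 1]")
  if (contrast <= 0 || contrast > 1) stop("contrast must be in (0, 1]")
  if (is.null(signal_alpha)) {
    signal_alpha <- if (n_signal_proteins > 1L)
      seq(0.8, 1.2, length.out = n_signal_proteins) else rep(1, n_signal_proteins)
  }
  if (length(signal_alpha) != n_signal_proteins)
    stop("signal_alpha must have length n_signal_proteins")
  p <- list(slide_px = as.integer(slide_px), tile_px = as.integer(tile_px),
            tissue_fraction_range = tissue_fraction_range,
            tumor_fraction_range = tumor_fraction_range,
            tumor_prevalence = tumor_prevalence,
            n_proteins = as.integer(n_proteins),
            n_signal_proteins = as.integer(n_signal_proteins),
            signal_alpha = signal_alpha, noise_sd = noise_sd,
            noise_protein_sd = noise_protein_sd,
            cox_coefficients = cox_coefficients,
            censoring_rate = censoring_rate, contrast = contrast,
            seed = as.integer(seed),
            protein_names = sprintf("protein_%d", seq_len(n_proteins)),
            her2_index = 1L, baseline_hazard = 0.1)
  class(p) <- "synthesis_params"
  p
}

# Threshold a smooth field so that `target` of the `inside` pixels exceed it.
.threshold_fraction <- function(field, inside, target) {
  out <- matrix(FALSE, nrow(field), ncol(field))
  if (target <= 0 || !any(inside)) return(out)
  v <- field[inside]
  cut <- stats::quantile(v, probs = 1 - target, names = FALSE, type = 7)
  out[inside] <- field[inside] > cut
  # quantile ties can under/overshoot; fall back to exact rank selection
  need <- round(target * sum(inside))
  if (sum(out) != need && need >= 1) {
    ord <- order(v, decreasing = TRUE)
    sel <- logical(length(v)); sel[ord[seq_len(need)]] <- TRUE
    out[inside] <- sel
  }
  out
}

#' Generate one synthetic slide
#'
#' Pure function of \code{(params, slide_seed)}: draws the tissue blob, the
#' tumor subregions, the H&E-like raster texture, the protein panel, the
#' censored survival record, and the responder flag.  The stored
#' \code{tumor_fraction} is recomputed exactly from the generated masks.
#'
#' The responder flag returned here is taken against the population median of
#' the HER2-like protein (slope times the expected tumor fraction);
#' \code{\link{make_cohort}} replaces it with the empirical cohort-median
#' split once all slides exist.
#'
#' @param params A \code{\link{synthesis_params}} object.
#' @param slide_seed Integer distinguishing slides under one master seed.
#' @return An object of class \code{synthetic_slide} with fields
#'   \code{raster} (\[h,w,3\] in \[0,1\], 8-bit quantized), \code{tissue_mask},
#'   \code{tumor_mask} (logical matrices, tumor a subset of tissue),
#'   \code{tumor_fraction}, \code{latent} (features driving survival), and
#'   \code{labels} (tumor_flag, proteins, survival, responder).
#' @export
make_slide <- function(params, slide_seed = 1L) {
  stopifnot(inherits(params, "synthesis_params"))
  px <- params$slide_px
  if (px < 2L * params$tile_px)
    stop("slide_px must be at least 2 * tile_px")
  set.seed(derive_seed(params$seed, slide_seed))

  # tissue blob: smooth noise plus a radial bias keeps it compact
  tf_target <- stats::runif(1, params$tissue_fraction_range[1], params$tissue_fraction_range[2])
  cy <- (seq_len(px) - px / 2) / px
  r2 <- outer(cy^2, cy^2, "+")
  field <- smooth_field(px, 6L) + 2.5 * (0.25 - r2)
  tissue <- .threshold_fraction(field, matrix(TRUE, px, px), tf_target)

  # tumor subregions inside tissue
  is_tumor <- stats::runif(1) < params$tumor_prevalence
  tu_target <- if (is_tumor)
    stats::runif(1, params$tumor_fraction_range[1], params$tumor_fraction_range[2]) else 0
  tumor <- .threshold_fraction(smooth_field(px, 8L), tissue, tu_target)
  tumor_fraction <- if (any(tissue)) sum(tumor) / sum(tissue) else 0

  # raster: pale background, eosin-pink tissue, hue-shifted speckled tumor
  ctr <- params$contrast
  col_bg <- c(0.96, 0.95, 0.97)
  col_tis <- c(0.86, 0.62, 0.78)
  col_tum <- col_tis + ctr * (c(0.60, 0.38, 0.72) - col_tis)
  col_nuc <- c(0.38, 0.22, 0.50)
  col_nuc_tum <- col_nuc + ctr * (c(0.22, 0.10, 0.34) - col_nuc)
  speckle_norm <- 0.02
  speckle_tum <- 0.02 + ctr * 0.10

  u_speck <- matrix(stats::runif(px * px), px, px)
  speck <- (tissue & !tumor & u_speck < speckle_norm) | (tumor & u_speck < speckle_tum)
  grain <- matrix(stats::rnorm(px * px, 0, 0.015), px, px)
  raster <- array(0, c(px, px, 3))
  for (k in 1:3) {
    ch <- matrix(col_bg[k], px, px)
    ch[tissue] <- col_tis[k]
    ch[tumor] <- col_tum[k]
    ch[speck & !tumor] <- col_nuc[k]
    ch[speck & tumor] <- col_nuc_tum[k]
    raster[, , k] <- ch + grain
  }
  raster <- quantize8(raster)

  # latent slide features: tumor fraction and nuclear-speckle density in tissue
  speck_density <- if (any(tissue)) sum(speck & tissue) / sum(tissue) else 0
  latent <- c(tumor_fraction = tumor_fraction, speckle_density = speck_density)

  # protein panel: signal proteins linear in tumor fraction, rest pure noise
  k_sig <- params$n_signal_proteins
  prot <- numeric(params$n_proteins)
  if (k_sig > 0)
    prot[seq_len(k_sig)] <- params$signal_alpha * tumor_fraction +
      stats::rnorm(k_sig, 0, params$noise_sd)
  if (params$n_proteins > k_sig)
    prot[(k_sig + 1L):params$n_proteins] <-
      stats::rnorm(params$n_proteins - k_sig, 0, params$noise_protein_sd)
  names(prot) <- params$protein_names

  # survival: exponential PH on the latent features, independent censoring
  lp <- sum(params$cox_coefficients * latent)
  rate <- params$baseline_hazard * exp(lp)
  t_event <- stats::rexp(1, rate)
  cr <- params$censoring_rate
  if (cr > 0) {
    t_cens <- stats::rexp(1, rate * cr / (1 - cr))
    surv <- list(time = min(t_event, t_cens), event = as.integer(t_event <= t_cens))
  } else {
    surv <- list(time = t_event, event = 1L)
  }

  her2 <- prot[params$her2_index]
  pop_median <- params$signal_alpha[params$her2_index] *
    params$tumor_prevalence * mean(params$tumor_fraction_range)
  labels <- list(tumor_flag = tumor_fraction > 0, proteins = prot,
                 survival = surv, responder = unname(her2 < pop_median))

  structure(list(raster = raster, tissue_mask = tissue, tumor_mask = tumor,
                 tumor_fraction = tumor_fraction, latent = latent,
                 labels = labels, slide_seed = as.integer(slide_seed)),
            class = "synthetic_slide")
}

#' @export
print.synthetic_slide <- function(x, ...) {
  cat(sprintf("<synthetic_slide> %dx%d px | tissue %.1f%% | tumor fraction %.3f | %s\n",
              nrow(x$raster), ncol(x$raster),
              100 * mean(x$tissue_mask), x$tumor_fraction,
              if (x$labels$tumor_flag) "tumor" else "normal"))
  invisible(x)
}

#' Generate and persist a synthetic cohort
#'
#' Writes every slide (RGB PNG), its tissue and tumor masks (single-channel
#' PNG), and a manifest CSV to \code{dir}, then partitions slides into
#' train/validation/test by 60/20/20 using the master seed.  When
#' \code{n_slides} is too small for a three-way split, slides fill train
#' first, then validation, then test, with a warning.  Responder flags are
#' recomputed as "HER2-like protein below the empirical cohort median".
#'
#' @param params A \code{\link{synthesis_params}} object.
#' @param n_slides Number of slides (one synthetic patient per slide).
#' @param dir Output directory; created if absent.
#' @return The manifest as a data.frame of class \code{cohort_manifest} with
#'   columns slide_id, patient_id, path, tissue_mask_path, tumor_mask_path,
#'   split, tumor_flag, tumor_fraction, one column per protein, surv_time,
#'   surv_event, responder.  Attributes carry the params and HER2-like name.
#' @export
make_cohort <- function(params, n_slides, dir = tempfile("cohort")) {
  stopifnot(inherits(params, "synthesis_params"), n_slides >= 1)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("could not create cohort directory: ", dir)

  rows <- vector("list", n_slides)
  her2 <- numeric(n_slides)
  latents <- matrix(0, n_slides, 2)
  for (i in seq_len(n_slides)) {
    sl <- make_slide(params, i)
    sid <- sprintf("slide_%03d", i)
    path <- file.path(dir, paste0(sid, ".png"))
    tis_path <- file.path(dir, paste0(sid, "_tissue.png"))
    tum_path <- file.path(dir, paste0(sid, "_tumor.png"))
    png::writePNG(sl$raster, path)
    png::writePNG(sl$tissue_mask * 1, tis_path)
    png::writePNG(sl$tumor_mask * 1, tum_path)
    her2[i] <- sl$labels$proteins[params$her2_index]
    latents[i, ] <- sl$latent
    rows[[i]] <- data.frame(
      slide_id = sid, patient_id = sprintf("patient_%03d", i),
      path = path, tissue_mask_path = tis_path, tumor_mask_path = tum_path,
      split = NA_character_, tumor_flag = sl$labels$tumor_flag,
      tumor_fraction = sl$tumor_fraction,
      as.list(sl$labels$proteins),
      surv_time = sl$labels$survival$time, surv_event = sl$labels$survival$event,
      responder = NA, check.names = FALSE, stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  manifest$responder <- her2 < stats::median(her2)

  # seeded 60/20/20 split, filling train, then val, then test
  n_tr <- floor(0.6 * n_slides); n_va <- floor(0.2 * n_slides)
  n_te <- floor(0.2 * n_slides)
  left <- n_slides - n_tr - n_va - n_te
  add <- c(min(left, 1), min(max(left - 1, 0), 1), max(left - 2, 0))
  sizes <- c(n_tr, n_va, n_te) + add
  if (any(sizes[2:3] == 0))
    warning("cohort too small for a full 60/20/20 split; filling train, then val, then test")
  set.seed(derive_seed(params$seed, 0L))
  perm <- sample.int(n_slides)
  manifest$split[perm] <- rep(c("train", "val", "test"), times = sizes)

  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  structure(manifest, class = c("cohort_manifest", "data.frame"),
            params = params, her2_name = params$protein_names[params$her2_index],
            dir = dir, latent = latents)
}

#' Column names of the protein panel in a manifest
#' @param manifest A cohort manifest (or any data.frame with protein_* columns).
#' @return Character vector of protein column names.
#' @export
protein_columns <- function(manifest) {
  grep("^protein_", names(manifest), value = TRUE)
}
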