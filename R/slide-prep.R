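#' Construct a slide raster object
#'
#' @param pixels RGB array \[h, w, 3\] with values in \[0, 1\] (grayscale is
#'   promoted to RGB, alpha dropped).
#' @param magnification Nominal objective magnification, one of
#'   \code{"x5"}, \code{"x10"}, \code{"x20"}, \code{"x40"}.
#' @param mpp Microns per pixel (optional metadata).
#' @param slide_id Identifier carried into downstream artifacts.
#' @return An object of class \code{wsi_slide}.
#' @export
wsi_slide <- function(pixels, magnification = "x40", mpp = NA_real_,
                      slide_id = "slide") {
  pixels <- as_rgb_array(pixels)
  magnification <- match.arg(magnification, c("x5", "x10", "x20", "x40"))
  d <- dim(pixels)
  if (d[1] < 1 || d[2] < 1) stop("slide must have positive dimensions")
  structure(list(pixels = pixels, width_px = d[2], height_px = d[1],
                 mpp = mpp, magnification = magnification,
                 slide_id = slide_id),
            class = "wsi_slide")
}

#' @export
print.wsi_slide <- function(x, ...) {
  cat(sprintf("<wsi_slide> %s: %d x %d px @ %s\n", x$slide_id,
              x$width_px, x$height_px, x$magnification))
  invisible(x)
}

#' Read a slide image from disk
#'
#' PNG and plain (non-pyramidal) TIFF rasters are supported; synthetic
#' cohorts are written as PNG.
#'
#' @param path Image file path.
#' @inheritParams wsi_slide
#' @return A \code{\link{wsi_slide}}.
#' @export
read_slide <- function(path, magnification = "x40", mpp = NA_real_,
                       slide_id = sub("\\.[^.]+$", "", basename(path))) {
  if (!file.exists(path)) stop("slide file not found: ", path)
  ext <- tolower(sub(".*\\.", "", path))
  pixels <- switch(ext,
    png = png::readPNG(path),
    tif = , tiff = {
      if (!requireNamespace("tiff", quietly = TRUE))
        stop("the 'tiff' package is required to read TIFF slides")
      tiff::readTIFF(path)
    },
    stop("unsupported slide format: .", ext))
  wsi_slide(pixels, magnification = magnification, mpp = mpp, slide_id = slide_id)
}

.mag_value <- function(m) as.integer(sub("^x", "", m))

#' Segment tissue from background by Otsu thresholding
#'
#' The slide is area-average downsampled, the Otsu threshold is computed on
#' the HSV saturation channel (white background has near-zero saturation),
#' and connected components smaller than \code{min_object_px} full-resolution
#' pixels are removed.
#'
#' @param slide A \code{\link{wsi_slide}}.
#' @param downsample Integer downsample factor for the mask grid.
#' @param min_object_px Minimum object area in full-resolution pixels; the
#'   threshold is rescaled to the mask grid (and is therefore inactive at
#'   coarse downsamples where such objects occupy less than one mask cell).
#' @return An object of class \code{tissue_mask}: logical \code{mask} of
#'   dimension \code{ceiling(slide dims / downsample)}, the Otsu
#'   \code{threshold} on \[0,1\], the \code{downsample} factor, and a
#'   \code{no_tissue} flag set for blank (zero-variance) images.
#' @export
segment_tissue <- function(slide, downsample = 8L, min_object_px = 64L) {
  stopifnot(inherits(slide, "wsi_slide"))
  downsample <- as.integer(downsample)
  img <- pad_to_multiple(slide$pixels, downsample, value = 1)
  small <- if (downsample > 1L) block_downsample(img, downsample) else img
  sat <- rgb_saturation(small)
  if (stats::sd(sat) < 1e-8) {
    return(structure(list(mask = matrix(FALSE, nrow(sat), ncol(sat)),
                          threshold = NA_real_, downsample = downsample,
                          no_tissue = TRUE), class = "tissue_mask"))
  }
  thr <- EBImage::otsu(sat, range = c(0, 1), levels = 256)
  mask <- sat > thr
  min_cells <- floor(min_object_px / downsample^2)
  if (min_cells >= 1 && any(mask)) {
    lab <- EBImage::bwlabel(mask)
    sizes <- tabulate(lab[lab > 0])
    keep <- which(sizes >= min_cells)
    mask <- matrix(lab %in% keep & lab > 0, nrow(mask), ncol(mask))
  }
  structure(list(mask = mask, threshold = thr, downsample = downsample,
                 no_tissue = !any(mask)), class = "tissue_mask")
}

#' @export
print.tissue_mask <- function(x, ...) {
  cat(sprintf("<tissue_mask> %d x %d @ 1/%d | otsu %.3f | tissue %.1f%%%s\n",
              nrow(x$mask), ncol(x$mask), x$downsample,
              if (is.na(x$threshold)) NaN else x$threshold,
              100 * mean(x$mask), if (x$no_tissue) " | NO TISSUE" else ""))
  invisible(x)
}

#' Tessellate a slide into a bag of fixed-size tiles
#'
#' Lays a non-overlapping grid (stride = \code{tile_px}, half-open
#' footprints \code{[x0, x0 + tile_px)}) over the slide, 0-based, row-major
#' (top row first, left to right).  Edge tiles that would exceed the slide
#' bounds are dropped.  A tile is retained iff its tissue fraction under the
#' mask is at least \code{min_tissue_frac}.
#'
#' @param slide A \code{\link{wsi_slide}}.
#' @param mask A \code{\link{segment_tissue}} result (dimensions must match
#'   the slide at the mask's stated downsample).
#' @param tile_px Tile side in pixels (>= 32).
#' @param min_tissue_frac Minimum in-mask fraction for a tile to be kept.
#' @return An object of class \code{tile_bag}: \code{tiles} array
#'   \[n, tile_px, tile_px, 3\], \code{coords} matrix with 0-based columns
#'   \code{x0, y0}, \code{tissue_frac}, \code{tile_px}, \code{slide_id},
#'   \code{magnification}.  An empty bag (n = 0) is valid.
#' @export
tessellate <- function(slide, mask, tile_px = 256L, min_tissue_frac = 0.5) {
  stopifnot(inherits(slide, "wsi_slide"), inherits(mask, "tissue_mask"))
  tile_px <- as.integer(tile_px)
  if (tile_px < 32L) stop("tile_px must be at least 32")
  ds <- mask$downsample
  expect_dim <- c(ceiling(slide$height_px / ds), ceiling(slide$width_px / ds))
  if (!all(dim(mask$mask) == expect_dim))
    stop(sprintf("mask dimensions %dx%d do not match slide %dx%d at downsample %d",
                 nrow(mask$mask), ncol(mask$mask), slide$height_px, slide$width_px, ds))

  xs <- seq(0L, slide$width_px - tile_px, by = tile_px)
  ys <- seq(0L, slide$height_px - tile_px, by = tile_px)
  if (slide$width_px < tile_px) xs <- integer(0)
  if (slide$height_px < tile_px) ys <- integer(0)

  coords <- NULL; fracs <- NULL; keep_tiles <- list()
  m <- mask$mask
  for (y0 in ys) for (x0 in xs) {          # row-major: y outer, x inner
    ri <- (floor(y0 / ds) + 1L):min(ceiling((y0 + tile_px) / ds), nrow(m))
    ci <- (floor(x0 / ds) + 1L):min(ceiling((x0 + tile_px) / ds), ncol(m))
    fr <- mean(m[ri, ci])
    if (fr >= min_tissue_frac) {
      keep_tiles[[length(keep_tiles) + 1L]] <-
        slide$pixels[(y0 + 1L):(y0 + tile_px), (x0 + 1L):(x0 + tile_px), , drop = FALSE]
      coords <- rbind(coords, c(x0, y0))
      fracs <- c(fracs, fr)
    }
  }
  n <- length(keep_tiles)
  tiles <- array(0, c(n, tile_px, tile_px, 3))
  for (i in seq_len(n)) tiles[i, , , ] <- keep_tiles[[i]]
  if (is.null(coords)) coords <- matrix(integer(0), 0, 2)
  colnames(coords) <- c("x0", "y0")
  structure(list(tiles = tiles, coords = coords,
                 tissue_frac = if (is.null(fracs)) numeric(0) else fracs,
                 tile_px = tile_px, slide_id = slide$slide_id,
                 magnification = slide$magnification),
            class = "tile_bag")
}

#' @export
print.tile_bag <- function(x, ...) {
  cat(sprintf("<tile_bag> %s: %d tiles of %dx%d @ %s\n", x$slide_id,
              nrow(x$coords), x$tile_px, x$tile_px, x$magnification))
  invisible(x)
}

# Lab-space channel means/sds of an RGB tile (rows of pixels).
.lab_stats <- function(tile) {
  m <- cbind(as.vector(tile[, , 1]), as.vector(tile[, , 2]), as.vector(tile[, , 3]))
  lab <- grDevices::convertColor(m, from = "sRGB", to = "Lab")
  list(mean = colMeans(lab), sd = apply(lab, 2, stats::sd), lab = lab)
}

# Stain statistics of a typical eosin-dominated H&E field, used when no
# explicit reference tile is supplied.
.he_preset <- list(mean = c(70, 25, -8), sd = c(12, 8, 5))

#' Reinhard color normalization of a tile bag
#'
#' Matches each tile's Lab-space channel means and standard deviations to a
#' reference (another tile, or the built-in H&E preset).  Output is clipped
#' to the valid range.  Grayscale tiles pass through with a warning.
#'
#' @param bag A \code{\link{tessellate}} bag.
#' @param reference A reference tile (RGB array) or the string
#'   \code{"he_default"} for the built-in preset.
#' @return The bag with normalized tiles.
#' @export
normalize_color <- function(bag, reference = "he_default") {
  stopifnot(inherits(bag, "tile_bag"))
  n <- dim(bag$tiles)[1]
  if (n == 0L) return(bag)
  ref <- if (is.character(reference)) {
    match.arg(reference, "he_default")
    .he_preset
  } else {
    s <- .lab_stats(as_rgb_array(reference)); list(mean = s$mean, sd = s$sd)
  }
  eps <- 1e-8
  for (i in seq_len(n)) {
    tile <- bag$tiles[i, , , ]
    if (max(abs(tile[, , 1] - tile[, , 2])) < eps &&
        max(abs(tile[, , 2] - tile[, , 3])) < eps) {
      warning("grayscale tile passed through unnormalized (index ", i, ")")
      next
    }
    st <- .lab_stats(tile)
    lab <- st$lab
    for (k in 1:3) {
      z <- if (st$sd[k] < eps) 0 else (lab[, k] - st$mean[k]) / st$sd[k]
      lab[, k] <- z * ref$sd[k] + ref$mean[k]
    }
    rgb <- grDevices::convertColor(lab, from = "Lab", to = "sRGB")
    tp <- dim(tile)[1]
    bag$tiles[i, , , ] <- array(clamp01(rgb), c(tp, tp, 3))
  }
  bag
}

#' Resample a slide to a lower nominal magnification
#'
#' Area-average downsamples so that tiles cut afterwards represent the
#' target magnification; factor-of-two relations are preserved (x40 to x20
#' halves the linear resolution).
#'
#' @param slide A \code{\link{wsi_slide}}.
#' @param target Target magnification (\code{"x5"} ... \code{"x40"}), at
#'   most the slide's native magnification.
#' @return A \code{\link{wsi_slide}} at the target magnification.
#' @export
set_magnification <- function(slide, target) {
  stopifnot(inherits(slide, "wsi_slide"))
  target <- match.arg(target, c("x5", "x10", "x20", "x40"))
  native <- .mag_value(slide$magnification)
  tv <- .mag_value(target)
  if (tv > native)
    stop(sprintf("target magnification %s exceeds native %s", target, slide$magnification))
  if (tv == native) return(slide)
  f <- native / tv
  wsi_slide(block_downsample(slide$pixels, f), magnification = target,
            mpp = if (is.na(slide$mpp)) NA_real_ else slide$mpp * f,
            slide_id = slide$slide_id)
}
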