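#' Spatially deconvolve tile attention onto the slide grid
#'
#' Paints each tile's footprint with its min-max rescaled attention score at
#' a stated downsample of the slide, yielding an interpretable heatmap.
#' Pixels not covered by any retained tile are missing (NA), not zero.
#' Slides whose tiles all share one attention value map to 0.5 by
#' convention.
#'
#' @param sf A \code{\link{gated_attention}} result carrying coordinates.
#' @param slide_dims c(height_px, width_px) of the source slide.
#' @param tile_px Tile side in pixels.
#' @param downsample Heatmap downsample factor.
#' @return Object of class \code{heatmap_raster}: \code{values} matrix in
#'   \[0, 1\] with NA outside tile footprints, and \code{downsample}.
#' @export
deconvolve <- function(sf, slide_dims, tile_px, downsample = 32L) {
  stopifnot(inherits(sf, "slide_feature"))
  if (is.null(sf$coords) || nrow(sf$coords) != length(sf$attention))
    stop("slide feature carries no tile coordinates")
  ds <- as.integer(downsample)
  h <- ceiling(slide_dims[1] / ds); w <- ceiling(slide_dims[2] / ds)
  a <- sf$attention
  rng <- max(a) - min(a)
  # a single tile is trivially the maximum; constant multi-tile slides have
  # no ordering information and map to mid-scale
  vals <- if (length(a) == 1L) 1
  else if (rng < 1e-12) rep(0.5, length(a))
  else (a - min(a)) / rng
  out <- matrix(NA_real_, h, w)
  for (i in seq_along(vals)) {
    x0 <- sf$coords[i, 1]; y0 <- sf$coords[i, 2]
    if (x0 < 0 || y0 < 0 || x0 + tile_px > slide_dims[2] || y0 + tile_px > slide_dims[1])
      stop(sprintf("tile at (%d, %d) lies outside the slide", x0, y0))
    ri <- (floor(y0 / ds) + 1L):ceiling((y0 + tile_px) / ds)
    ci <- (floor(x0 / ds) + 1L):ceiling((x0 + tile_px) / ds)
    out[ri, ci] <- vals[i]
  }
  structure(list(values = out, downsample = ds, tile_px = tile_px),
            class = "heatmap_raster")
}

#' @export
print.heatmap_raster <- function(x, ...) {
  cat(sprintf("<heatmap_raster> %d x %d @ 1/%d | %.1f%% covered\n",
              nrow(x$values), ncol(x$values), x$downsample,
              100 * mean(!is.na(x$values))))
  invisible(x)
}

# Map heat values in [0,1] to an RGB array with a blue-yellow-red ramp.
.heat_colors <- function(v) {
  ramp <- grDevices::colorRamp(c("#2c2cb0", "#39c0c4", "#f8e71c", "#d0021b"))
  rgb <- ramp(as.vector(v)) / 255
  array(rgb, c(dim(v), 3L))
}

#' Render an attention heatmap over the slide as a PNG overlay
#'
#' Alpha-blends the colored heatmap onto the downsampled slide; missing
#' heatmap pixels show the slide unchanged (missing is not zero heat).
#'
#' @param heatmap A \code{\link{deconvolve}} raster.
#' @param slide The source \code{\link{wsi_slide}}.
#' @param path Output PNG path.
#' @param alpha Blend weight of the heat colors in \[0, 1\].
#' @return The blended RGB array, invisibly; the file is written to
#'   \code{path}.
#' @export
export_overlay <- function(heatmap, slide, path, alpha = 0.5) {
  stopifnot(inherits(heatmap, "heatmap_raster"), inherits(slide, "wsi_slide"))
  ds <- heatmap$downsample
  base <- block_downsample(pad_to_multiple(slide$pixels, ds, value = 1), ds)
  if (!all(dim(base)[1:2] == dim(heatmap$values)))
    stop("heatmap and downsampled slide dimensions do not match")
  v <- heatmap$values
  filled <- !is.na(v)
  v0 <- v; v0[!filled] <- 0
  hc <- .heat_colors(v0)
  out <- base
  for (k in 1:3) {
    ch <- base[, , k]
    ch[filled] <- (1 - alpha) * ch[filled] + alpha * hc[, , k][filled]
    out[, , k] <- ch
  }
  out <- quantize8(out)
  png::writePNG(out, path)
  invisible(out)
}

#' Per-tile overlap fraction with a full-resolution mask
#'
#' Utility for evaluating attention maps against a planted (ground-truth)
#' mask: returns, for each tile, the fraction of its footprint covered by
#' the mask.
#'
#' @param mask Full-resolution logical matrix.
#' @param coords Tile coordinate matrix (0-based columns x0, y0).
#' @param tile_px Tile side in pixels.
#' @return Numeric vector of per-tile mask fractions.
#' @export
tile_mask_fraction <- function(mask, coords, tile_px) {
  vapply(seq_len(nrow(coords)), function(i) {
    x0 <- coords[i, 1]; y0 <- coords[i, 2]
    mean(mask[(y0 + 1):(y0 + tile_px), (x0 + 1):(x0 + tile_px)])
  }, 0)
}
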