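# helper: RGB image with a prescribed per-pixel saturation (max channel 1)
sat_image <- function(sat) {
  h <- nrow(sat); w <- ncol(sat)
  img <- array(1, c(h, w, 3))
  img[, , 2] <- 1 - sat
  img[, , 3] <- 1 - sat
  img
}

test_that("otsu threshold on a bimodal image matches exhaustive search", {
  set.seed(4)
  sat <- matrix(0, 64, 64)
  sat[, 1:32] <- 40 / 255
  sat[, 33:64] <- 200 / 255
  sl <- wsi_slide(sat_image(sat))
  tm <- segment_tissue(sl, downsample = 1)
  # brute-force oracle: every threshold maximizing the between-class
  # variance over all 256 levels (a bimodal plateau admits a range)
  v <- as.vector(sat)
  bc <- vapply((0:255) / 255, function(t) {
    w0 <- mean(v <= t); w1 <- 1 - w0
    if (w0 == 0 || w1 == 0) return(-Inf)
    w0 * w1 * (mean(v[v > t]) - mean(v[v <= t]))^2
  }, 0)
  maximizers <- ((0:255) / 255)[bc >= max(bc) - 1e-12]
  expect_gte(tm$threshold, min(maximizers) - 1.5 / 255)
  expect_lte(tm$threshold, max(maximizers) + 1.5 / 255)
  # mask separates the two halves
  expect_true(all(tm$mask[, 33:64]))
  expect_false(any(tm$mask[, 1:32]))
})

test_that("blank slides report no tissue instead of crashing", {
  sl <- wsi_slide(array(1, c(64, 64, 3)))
  tm <- segment_tissue(sl, downsample = 8)
  expect_true(tm$no_tissue)
  expect_false(any(tm$mask))
})

test_that("tessellation lays an exhaustive half-open row-major grid", {
  sl <- wsi_slide(array(0.5, c(256, 256, 3)))
  tm <- structure(list(mask = matrix(TRUE, 8, 8), threshold = 0.1,
                       downsample = 32L, no_tissue = FALSE), class = "tissue_mask")
  bag <- tessellate(sl, tm, tile_px = 64, min_tissue_frac = 0.5)
  expect_equal(nrow(bag$coords), 16)
  grid <- expand.grid(x0 = c(0, 64, 128, 192), y0 = c(0, 64, 128, 192))
  # row-major: y outer, x inner
  expect_equal(bag$coords[, "x0"], rep(c(0, 64, 128, 192), 4))
  expect_equal(bag$coords[, "y0"], rep(c(0, 64, 128, 192), each = 4))
  expect_true(all(dim(bag$tiles)[2:3] == 64))

  # full-background mask: empty bag is valid
  tm0 <- structure(list(mask = matrix(FALSE, 8, 8), threshold = 0.1,
                        downsample = 32L, no_tissue = TRUE), class = "tissue_mask")
  bag0 <- tessellate(sl, tm0, tile_px = 64)
  expect_equal(nrow(bag0$coords), 0)

  # mismatched mask dimensions are rejected
  tm_bad <- structure(list(mask = matrix(TRUE, 4, 8), threshold = 0.1,
                           downsample = 32L, no_tissue = FALSE), class = "tissue_mask")
  expect_error(tessellate(sl, tm_bad, 64), "dimensions")
})

test_that("retained tile count matches a brute-force overlap count", {
  fx <- desk_cohort()
  sl <- read_slide(fx$man$path[1], slide_id = "s1")
  tm <- segment_tissue(sl, downsample = 32)
  for (frac in c(0.25, 0.5, 0.9)) {
    bag <- tessellate(sl, tm, tile_px = 32, min_tissue_frac = frac)
    cnt <- 0
    for (y0 in seq(0, 224, 32)) for (x0 in seq(0, 224, 32)) {
      sub <- tm$mask[(y0 / 32 + 1), (x0 / 32 + 1)]
      if (mean(sub) >= frac) cnt <- cnt + 1
    }
    expect_equal(nrow(bag$coords), cnt)
  }
})

test_that("tiles never overlap and stay within bounds", {
  fx <- desk_cohort()
  bag <- fx$bags[[2]]
  if (nrow(bag$coords) > 1) {
    key <- paste(bag$coords[, 1], bag$coords[, 2])
    expect_false(any(duplicated(key)))
    expect_true(all(bag$coords %% 32 == 0))
    expect_true(all(bag$coords[, 1] + 32 <= 256 & bag$coords[, 2] + 32 <= 256))
  }
})

test_that("tissue segmentation recovers the planted mask (IoU >= 0.9)", {
  fx <- desk_cohort()
  ious <- vapply(seq_len(5), function(i) {
    sl <- read_slide(fx$man$path[i])
    tm <- segment_tissue(sl)                 # default settings
    truth <- png::readPNG(fx$man$tissue_mask_path[i]) > 0.5
    td <- wsimil:::block_downsample(truth * 1, tm$downsample) >= 0.5
    sum(tm$mask & td) / sum(tm$mask | td)
  }, 0)
  expect_true(all(ious >= 0.9))
})

test_that("reinhard normalization matches reference statistics", {
  set.seed(8)
  mk_bag <- function(tile) {
    sl <- wsi_slide(tile)
    tm <- structure(list(mask = matrix(TRUE, dim(tile)[1], dim(tile)[2]),
                         threshold = 0.1, downsample = 1L, no_tissue = FALSE),
                    class = "tissue_mask")
    tessellate(sl, tm, tile_px = dim(tile)[1], min_tissue_frac = 0)
  }
  tile <- array(runif(64 * 64 * 3, 0.2, 0.9), c(64, 64, 3))
  # identity: reference = tile itself
  out <- normalize_color(mk_bag(tile), reference = tile)
  expect_equal(out$tiles[1, , , ], tile, tolerance = 0.02)
  # constant tile mapped to a constant reference color
  const <- array(0, c(64, 64, 3))
  const[, , 1] <- 0.8; const[, , 2] <- 0.4; const[, , 3] <- 0.6
  ref <- array(0, c(64, 64, 3))
  ref[, , 1] <- 0.3; ref[, , 2] <- 0.7; ref[, , 3] <- 0.5
  outc <- normalize_color(mk_bag(const), reference = ref)
  expect_equal(outc$tiles[1, 1, 1, ], c(0.3, 0.7, 0.5), tolerance = 0.02)
  expect_lt(max(apply(outc$tiles[1, , , ], 3, sd)), 1e-6)
  # general case: output Lab moments equal the reference's (recomputed)
  ref2 <- array(runif(64 * 64 * 3, 0.1, 0.95), c(64, 64, 3))
  out2 <- normalize_color(mk_bag(tile), reference = ref2)
  st_out <- wsimil:::.lab_stats(out2$tiles[1, , , ])
  st_ref <- wsimil:::.lab_stats(ref2)
  expect_equal(st_out$mean, st_ref$mean, tolerance = 0.6)
  expect_equal(st_out$sd, st_ref$sd, tolerance = 0.6)
  # grayscale tile passes through with a warning
  gray <- array(rep(matrix(runif(64 * 64), 64), 3), c(64, 64, 3))
  expect_warning(outg <- normalize_color(mk_bag(gray)), "grayscale")
  expect_equal(outg$tiles[1, , , ], gray)
})

test_that("magnification changes preserve factor-of-two tiling relations", {
  set.seed(2)
  px <- array(runif(512 * 512 * 3), c(512, 512, 3))
  sl40 <- wsi_slide(px, magnification = "x40")
  sl20 <- set_magnification(sl40, "x20")
  expect_equal(c(sl20$height_px, sl20$width_px), c(256, 256))
  expect_identical(set_magnification(sl40, "x40"), sl40)
  expect_error(set_magnification(sl20, "x40"), "exceeds")
  # tessellation oracle: x40 slide at x10 tiles like a quarter-size raster
  sl10 <- set_magnification(sl40, "x10")
  mk_full_mask <- function(s) structure(
    list(mask = matrix(TRUE, ceiling(s$height_px / 32), ceiling(s$width_px / 32)),
         threshold = 0.1, downsample = 32L, no_tissue = FALSE),
    class = "tissue_mask")
  b10 <- tessellate(sl10, mk_full_mask(sl10), tile_px = 32, min_tissue_frac = 0)
  direct <- wsi_slide(wsimil:::block_downsample(px, 4), magnification = "x10")
  bd <- tessellate(direct, mk_full_mask(direct), tile_px = 32, min_tissue_frac = 0)
  expect_equal(nrow(b10$coords), nrow(bd$coords))
})
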