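test_that("cosine similarity follows its closed form", {
  expect_equal(cosine_sim(c(2, 3, 1), c(2, 3, 1), tau = 1), 1.0)
  expect_equal(cosine_sim(c(1, 0), c(0, 1), tau = 0.5), 0.0)
  expect_equal(cosine_sim(c(1, 1), c(1, 0), tau = 1), 1 / sqrt(2))
  expect_equal(cosine_sim(c(1, 1), c(1, 0), tau = 0.5), 2 / sqrt(2))
  expect_error(cosine_sim(c(0, 0), c(1, 0)), "zero vector")
  expect_error(cosine_sim(c(1, 0), c(1, 0), tau = 0), "positive")
})

test_that("InfoNCE loss matches closed-form cases", {
  q <- memory_queue(2, 3)
  q$buffer <- rbind(c(0, 1, 0), c(0, 0, 1))
  z <- c(1, 0, 0)
  # z = z_pos, two orthogonal unit negatives, tau = 1:
  # -log(e / (e + 2)), since exp(sim) of each negative is exp(0) = 1
  expect_equal(info_nce_loss(z, z, q, tau = 1), -log(exp(1) / (exp(1) + 2)))
  # everything orthogonal: uniform softmax over K + 1
  zp <- c(0, 1, 0)
  q2 <- memory_queue(4, 3)
  q2$buffer <- rbind(c(0, 0, 1), c(0, 0, -1), c(0, -1, 0), c(0, 1, 0))
  z3 <- c(1, 0, 0)
  expect_equal(info_nce_loss(z3, zp, q2, tau = 1), log(4 + 1))
  # literal (negatives-only) denominator
  expect_equal(info_nce_loss(z3, zp, q2, tau = 1, denominator = "literal"), log(4))
  expect_error(info_nce_loss(z3, zp, q2, tau = -1), "positive")
})

test_that("mean InfoNCE over random high-dimensional vectors is near log(K+1)", {
  set.seed(31)
  d <- 128; K <- 64
  q <- memory_queue(K, d)
  losses <- replicate(200, {
    z <- rnorm(d); zp <- rnorm(d)
    info_nce_loss(z, zp, q, tau = 1)
  })
  # in high dimension all similarities are ~0, so the softmax is ~uniform
  expect_equal(mean(losses), log(K + 1), tolerance = 0.05)
})

test_that("momentum update has copy and fixed-point behavior; queue is FIFO", {
  fx <- desk_cohort()
  enc <- pretrain(fx$bags[1], epochs = 1, batch_size = 8, queue_K = 8,
                  tile_sample = 0.3, seed = 3)
  # m = 0 copies the online parameters
  e0 <- momentum_update(enc, 0)
  expect_identical(e0$key_params, e0$params)
  # key == online is a fixed point for any m
  e1 <- momentum_update(momentum_update(e0, 0.999), 0.999)
  expect_equal(e1$key_params, e0$params, tolerance = 1e-12)
  expect_error(momentum_update(enc, 1), "\\[0, 1\\)")

  # FIFO replay oracle: the buffer holds exactly the last K keys in order
  K <- 6; dz <- 4
  qq <- memory_queue(K, dz, seed = 5)
  all_keys <- matrix(rnorm(30 * dz), 30)
  all_keys <- all_keys / sqrt(rowSums(all_keys^2))
  for (b in split(seq_len(30), rep(1:10, each = 3)))
    qq <- queue_push(qq, all_keys[b, ])
  expected <- all_keys[25:30, ]          # last K insertions
  ring <- rbind(qq$buffer[qq$head:K, , drop = FALSE],
                qq$buffer[seq_len(qq$head - 1), , drop = FALSE])
  expect_equal(ring, expected, ignore_attr = TRUE)
  expect_equal(sqrt(rowSums(qq$buffer^2)), rep(1, K))
})

test_that("pretraining is deterministic and echoes its configuration", {
  fx <- desk_cohort()
  small <- fx$bags[1:2]
  e1 <- pretrain(small, epochs = 1, batch_size = 8, queue_K = 16, seed = 9)
  e2 <- pretrain(small, epochs = 1, batch_size = 8, queue_K = 16, seed = 9)
  expect_identical(e1$log$loss, e2$log$loss)
  expect_identical(e1$params, e2$params)
  expect_equal(e1$config$lr, 0.03)
  expect_equal(e1$config$weight_decay, 1e-4)
  expect_equal(e1$config$sgd_momentum, 0.9)
})

test_that("pretraining makes progress and separates augmented pairs", {
  enc <- desk_encoder()
  expect_lt(mean(enc$log$loss[-1]), enc$log$loss[1])
  # similarity gap: positive (augmented) pairs vs mismatched pairs
  set.seed(12)
  tiles <- wsimil:::.collect_tiles(desk_cohort()$bags)
  n <- 50; idx <- sample(length(tiles), n)
  cfg <- enc$config; im <- wsimil:::.im2col_index(cfg$in_px)
  A <- array(0, c(n, cfg$in_px, cfg$in_px, 3)); B <- A
  for (j in seq_len(n)) {
    A[j, , , ] <- wsimil:::.augment_tile(tiles[[idx[j]]], cfg$in_px)
    B[j, , , ] <- wsimil:::.augment_tile(tiles[[idx[j]]], cfg$in_px)
  }
  ha <- wsimil:::.encoder_forward(enc$params, cfg, A, im)$h
  hb <- wsimil:::.encoder_forward(enc$params, cfg, B, im)$h
  cs <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  pos <- mean(vapply(seq_len(n), function(j) cs(ha[j, ], hb[j, ]), 0))
  shift <- c(seq_len(n)[-1], 1)
  rnd <- mean(vapply(seq_len(n), function(j) cs(ha[j, ], hb[shift[j], ]), 0))
  expect_gt(pos, rnd)
})

test_that("embedding is pure, ordered, and handles empty bags", {
  fx <- desk_cohort()
  enc <- desk_encoder()
  bag <- fx$bags[[1]]
  expect_gte(nrow(bag$coords), 2)
  # duplicate a tile: identical embedding rows
  bag2 <- bag
  bag2$tiles[2, , , ] <- bag2$tiles[1, , , ]
  H <- embed_tiles(bag2, enc)
  expect_equal(H[1, ], H[2, ])
  expect_equal(nrow(H), nrow(bag$coords))
  # empty bag: 0 x d matrix
  empty <- bag; empty$tiles <- array(0, c(0, 32, 32, 3))
  empty$coords <- matrix(integer(0), 0, 2)
  He <- embed_tiles(empty, enc)
  expect_equal(dim(He), c(0, enc$config$d))
})

test_that("encoder and InfoNCE gradients match finite differences", {
  cfg <- wsimil:::.encoder_config(8L, 2L, 4L, 3L)
  par <- wsimil:::.encoder_init(cfg, 1)
  idx <- wsimil:::.im2col_index(8L)
  set.seed(5)
  X <- array(runif(3 * 8 * 8 * 3), c(3, 8, 8, 3))
  Kn <- matrix(rnorm(9), 3); Kn <- Kn / sqrt(rowSums(Kn^2))
  buf <- matrix(rnorm(15), 5); buf <- buf / sqrt(rowSums(buf^2))
  lossfun <- function(p) {
    f <- wsimil:::.encoder_forward(p, cfg, X, idx, project = TRUE)
    wsimil:::.nce_batch(f$z, Kn, buf, 0.2)$loss
  }
  f <- wsimil:::.encoder_forward(par, cfg, X, idx, project = TRUE, keep_cache = TRUE)
  nce <- wsimil:::.nce_batch(f$z, Kn, buf, 0.2)
  gr <- wsimil:::.encoder_backward(par, cfg, f$cache, dZ = nce$dQn)
  for (nm in names(gr)) {
    for (k in seq_len(min(length(par[[nm]]), 6))) {
      e <- 1e-5
      pp <- par; pp[[nm]][k] <- pp[[nm]][k] + e; f1 <- lossfun(pp)
      pp[[nm]][k] <- pp[[nm]][k] - 2 * e; f2 <- lossfun(pp)
      expect_lt(abs((f1 - f2) / (2 * e) - gr[[nm]][k]), 1e-5)
    }
  }
})
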