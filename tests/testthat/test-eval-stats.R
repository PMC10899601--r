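test_that("pearson correlation matches hand-computed cases", {
  x <- c(1, 2, 3, 4)
  expect_equal(pearson(x, 2 * x + 1)$r, 1.0)
  expect_equal(pearson(x, -x)$r, -1.0)
  ct <- pearson(x, c(1, 3, 2, 4))
  expect_equal(ct$r, 0.8)
  # p from the t-transform with n - 2 df, recomputed independently
  tstat <- 0.8 * sqrt(2) / sqrt(1 - 0.64)
  expect_equal(ct$p, 2 * pt(-abs(tstat), df = 2))
  expect_error(pearson(c(1, 1, 1), c(1, 2, 3)), "zero-variance")
  expect_error(pearson(1:2, 1:2), "n >= 3")
})

test_that("BH adjustment implements the step-up rule", {
  expect_equal(bh_adjust(0.03)$p_adj, 0.03)
  res <- bh_adjust(c(0.005, 0.01, 0.03, 0.04), alpha = 0.05)
  # brute-force step-up oracle: largest i with p_(i) <= i * alpha / m
  p <- sort(c(0.005, 0.01, 0.03, 0.04))
  k <- max(which(p <= seq_along(p) * 0.05 / 4))
  expect_equal(sum(res$reject), k)
  expect_true(all(res$reject))
  # adjusted values are monotone in sorted order
  set.seed(41)
  pv <- runif(50)
  adj <- bh_adjust(pv)$p_adj
  expect_true(all(diff(adj[order(pv)]) >= -1e-12))
  expect_true(all(adj >= pv))
  expect_length(bh_adjust(numeric(0))$p_adj, 0)
  expect_error(bh_adjust(c(0.5, 0)), "\\(0, 1\\]")
})

test_that("BH controls the false-positive fraction under the null", {
  set.seed(42)
  m <- 200
  pv <- vapply(seq_len(m), function(i) pearson(rnorm(30), rnorm(30))$p, 0)
  expect_lte(mean(bh_adjust(pv, 0.05)$reject), 0.05 + 0.02)
})

test_that("ROC AUC follows the rank formulation with tie handling", {
  expect_equal(roc_auc(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1)), 1.0)
  expect_equal(roc_auc(rep(0.5, 6), c(0, 1, 0, 1, 0, 1)), 0.5)
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 0, 1, 0)), 0.75)
  expect_error(roc_auc(1:3, c(1, 1, 1)), "both classes")
  # symmetry for tie-free scores
  set.seed(43)
  s <- rnorm(40); y <- rbinom(40, 1, 0.5)
  y[1:2] <- c(0, 1)
  expect_equal(roc_auc(s, y) + roc_auc(-s, y), 1.0)
  # brute-force pairwise oracle
  auc_brute <- function(s, y) {
    pos <- which(y == 1); neg <- which(y == 0)
    tot <- 0
    for (i in pos) for (j in neg)
      tot <- tot + (s[i] > s[j]) + 0.5 * (s[i] == s[j])
    tot / (length(pos) * length(neg))
  }
  s2 <- sample(1:5, length(y), replace = TRUE)
  expect_equal(roc_auc(s2, y), auc_brute(s2, y))
})

test_that("roc_auc agrees with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(44)
  s <- rnorm(60); y <- rbinom(60, 1, 0.4); y[1:2] <- c(0, 1)
  ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE, direction = "<")))
  expect_equal(roc_auc(s, y), ref, tolerance = 1e-12)
})

test_that("confusion matrix and accuracy match a counting oracle", {
  y <- c(0, 1, 1, 0)
  r1 <- confusion_and_accuracy(y, y)
  expect_equal(unname(r1$matrix), matrix(c(2, 0, 0, 2), 2, byrow = TRUE))
  expect_equal(r1$accuracy, 1.0)
  r2 <- confusion_and_accuracy(1 - y, y)
  expect_equal(diag(r2$matrix), c(`0` = 0, `1` = 0))
  expect_equal(r2$accuracy, 0.0)
  set.seed(45)
  p <- rbinom(50, 1, 0.5); t <- rbinom(50, 1, 0.5)
  r3 <- confusion_and_accuracy(p, t)
  expect_equal(r3$matrix["1", "0"], sum(t == 1 & p == 0))
  expect_equal(r3$accuracy, mean(p == t))
  expect_error(confusion_and_accuracy(1:3, 1:4), "agree in length")
})

test_that("concordance index matches exhaustive pair enumeration", {
  # perfectly anti-ordered scores with times, all events
  rec <- survival_records(c(1, 2, 3, 4), rep(1, 4), cbind(x = 1:4))
  expect_equal(c_index(c(4, 3, 2, 1), rec), 1.0)
  expect_equal(c_index(rep(2, 4), rec), 0.5)
  # n = 6 mixed censoring vs brute force
  rec6 <- survival_records(c(2, 5, 3, 3, 8, 1), c(1, 0, 1, 0, 1, 1),
                           cbind(x = rnorm(6)))
  sc <- c(0.3, -1, 2, 0.5, 0, 1.2)
  brute <- function(scores, time, event) {
    conc <- 0; tot <- 0
    for (i in 1:6) for (j in 1:6) {
      if (i == j || event[i] != 1) next
      if (time[j] > time[i] || (time[j] == time[i] && event[j] == 0)) {
        tot <- tot + 1
        conc <- conc + (scores[i] > scores[j]) + 0.5 * (scores[i] == scores[j])
      }
    }
    conc / tot
  }
  expect_equal(c_index(sc, rec6), brute(sc, rec6$time, rec6$event))
  # invariant under strictly monotone transforms
  expect_equal(c_index(exp(sc), rec6), c_index(sc, rec6))
  expect_error(c_index(1, survival_records(1, 0, cbind(x = 1))), "no events|comparable")
})

test_that("c_index agrees with the survival package", {
  skip_if_not_installed("survival")
  rec <- sim_surv(120, seed = 46)
  fit <- cox_fit(rec)
  sc <- risk_score(fit, as.matrix(rec[, attr(rec, "covariates")]))
  ref <- survival::concordance(
    survival::coxph(survival::Surv(rec$time, rec$event) ~ rec$trt))$concordance
  expect_equal(c_index(sc, rec), ref, tolerance = 1e-10)
})

test_that("k-fold assignment is seeded, balanced, and leakage-free", {
  ids <- sprintf("pt%02d", 1:10)
  f <- kfold(ids, 5, seed = 3)
  expect_true(all(table(f) == 2))
  expect_identical(f, kfold(ids, 5, seed = 3))
  expect_false(identical(f, kfold(ids, 5, seed = 4)))
  # a patient with 3 slides lands in exactly one fold
  slides <- c(ids, "pt03", "pt03")
  fs <- kfold(slides, 5, seed = 3)
  expect_length(unique(fs[slides == "pt03"]), 1)
  expect_error(kfold(ids, 11), "exceeds")
  expect_error(kfold(ids, 1), "at least 2")
})
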