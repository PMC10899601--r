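test_that("partial likelihood matches hand enumeration and brute force", {
  # all censored: empty event sum
  r0 <- survival_records(c(1, 2), c(0, 0), cbind(x = c(1, 2)))
  expect_warning(v0 <- neg_log_partial_likelihood(0.5, r0), "no events")
  expect_equal(v0, 0)
  # two subjects, both events, theta'x = 0: log 2
  r2 <- survival_records(c(1, 2), c(1, 1), cbind(x = c(0, 0)))
  expect_equal(neg_log_partial_likelihood(0, r2), log(2))
  # brute-force double loop on random data
  set.seed(33)
  for (rep in 1:5) {
    n <- 5
    rec <- survival_records(runif(n, 1, 10), rbinom(n, 1, 0.6) | c(1, rep(0, n - 1)),
                            matrix(rnorm(n * 2), n))
    th <- rnorm(2)
    X <- as.matrix(rec[, attr(rec, "covariates")])
    lp <- X %*% th
    naive <- 0
    for (i in seq_len(n)) {
      if (rec$event[i] != 1) next
      denom <- 0
      for (j in seq_len(n)) if (rec$time[j] >= rec$time[i]) denom <- denom + exp(lp[j])
      naive <- naive - (lp[i] - log(denom))
    }
    expect_lt(abs(neg_log_partial_likelihood(th, rec) - naive), 1e-10)
  }
})

test_that("partial likelihood depends only on linear-predictor differences", {
  set.seed(34)
  rec <- sim_surv(40, seed = 34)
  # adding a constant to every theta'x leaves the loss unchanged: append an
  # all-ones covariate and put weight on it
  X <- as.matrix(rec[, attr(rec, "covariates"), drop = FALSE])
  rec2 <- survival_records(rec$time, rec$event, cbind(X, one = 1))
  expect_equal(neg_log_partial_likelihood(c(0.7, 0), rec2),
               neg_log_partial_likelihood(c(0.7, 5), rec2), tolerance = 1e-9)
})

test_that("analytic gradient matches central finite differences", {
  set.seed(35)
  n <- 5
  rec <- survival_records(runif(n, 1, 8), c(1, 1, 0, 1, 0), matrix(rnorm(n * 2), n))
  th <- c(0.4, -0.6)
  X <- as.matrix(rec[, attr(rec, "covariates")])
  g <- wsimil:::.cox_derivs(th, rec$time, rec$event, X)$grad
  for (k in 1:2) {
    e <- 1e-6
    t1 <- th; t1[k] <- t1[k] + e
    t2 <- th; t2[k] <- t2[k] - e
    fd <- (neg_log_partial_likelihood(t1, rec) - neg_log_partial_likelihood(t2, rec)) / (2 * e)
    expect_lt(abs(g[k] - fd), 1e-5)
  }
})

test_that("cox_fit agrees with an independent Breslow implementation", {
  skip_if_not_installed("survival")
  rec <- sim_surv(300, seed = 36)
  fit <- cox_fit(rec)
  ref <- survival::coxph(survival::Surv(rec$time, rec$event) ~ rec$trt,
                         ties = "breslow")
  expect_equal(unname(coef(fit)), unname(coef(ref)), tolerance = 1e-6)
  expect_equal(unname(sqrt(diag(vcov(fit)))), unname(sqrt(diag(vcov(ref)))),
               tolerance = 1e-6)
  # stationarity: refitting from the optimum moves nothing
  expect_true(fit$converged)
  expect_lt(fit$gradient_norm, 1e-6)
  # Breslow cumulative baseline: nondecreasing, one jump per event time
  expect_true(all(diff(fit$baseline$cumhaz) >= 0))
  expect_equal(nrow(fit$baseline), length(unique(rec$time[rec$event == 1])))
  expect_true(all(fit$baseline$hazard >= 0))
})

test_that("coefficients recover a known hazard ratio", {
  rec <- sim_surv(500, theta = log(3), seed = 37)
  fit <- cox_fit(rec)
  se <- sqrt(diag(vcov(fit)))
  expect_lt(abs(coef(fit) - log(3)) / se, 3)
  u <- univariate_hr(rec)
  expect_equal(u$hr, unname(exp(coef(fit))))
  expect_true(u$lo95 < u$hi95)
})

test_that("null-covariate Wald interval covers HR = 1 at its nominal rate", {
  cover <- vapply(1:25, function(i) {
    set.seed(400 + i)
    n <- 80
    x <- rnorm(n)
    tm <- rexp(n, 0.1)
    cen <- rexp(n, 0.05)
    rec <- survival_records(pmin(tm, cen), as.integer(tm <= cen), cbind(x = x))
    u <- univariate_hr(rec)
    u$lo95 <= 1 && 1 <= u$hi95
  }, TRUE)
  expect_gte(mean(cover), 0.8)
})

test_that("risk scores and stratification follow their contracts", {
  rec <- sim_surv(60, seed = 38)
  fit <- cox_fit(rec)
  expect_equal(risk_score(fit, matrix(0, 1, 1)), 0)
  fit2 <- fit
  fit2$coefficients <- c(a = 1, b = -1)
  fit2$vcov <- diag(2)
  expect_equal(risk_score(fit2, c(2, 3)), -1)
  expect_error(risk_score(fit2, c(1, 2, 3)), "dimension")
  # order invariant to a constant shift of the covariates
  set.seed(39)
  X <- matrix(rnorm(20), 10, 2)
  s1 <- risk_score(fit2, X)
  s2 <- risk_score(fit2, X + 5)
  expect_equal(order(s1), order(s2))

  g <- stratify(c(1, 2, 3, 4))
  expect_equal(as.character(g), c("low", "low", "high", "high"))
  expect_equal(attr(g, "cutpoint"), 2.5)
  # ties at the cutpoint go low
  g2 <- stratify(c(1, 2, 2, 3))
  expect_equal(as.character(g2), c("low", "low", "low", "high"))
  expect_error(stratify(rep(1, 4)), "degenerate")
  expect_error(stratify(1), "at least 2")
  # strong effect (continuous covariate so the median split is non-degenerate)
  set.seed(40)
  n <- 300
  xx <- rnorm(n)
  tev <- rexp(n, 0.1 * exp(1.5 * xx)); cen <- rexp(n, 0.04)
  rec2 <- survival_records(pmin(tev, cen), as.integer(tev <= cen), cbind(x = xx))
  f2 <- cox_fit(rec2)
  sc <- risk_score(f2, as.matrix(rec2[, attr(rec2, "covariates")]))
  gg <- stratify(sc)
  expect_gt(mean(rec2$event[gg == "high"]), mean(rec2$event[gg == "low"]))
})
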