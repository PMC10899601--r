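#' Assemble survival records
#'
#' @param time Positive follow-up times.
#' @param event Event indicators (1 = death event, 0 = censored).
#' @param x Covariate matrix (rows = patients) or vector.
#' @param patient_id Optional identifiers.
#' @return data.frame of class \code{survival_records}.
#' @export
survival_records <- function(time, event, x, patient_id = NULL) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- sprintf("x%d", seq_len(ncol(x)))
  if (any(!is.finite(time)) || any(time <= 0)) stop("times must be finite and positive")
  if (!all(event %in% c(0, 1))) stop("event indicators must be 0/1")
  if (any(!is.finite(x))) stop("covariates must be finite")
  if (length(time) != length(event) || length(time) != nrow(x))
    stop("time, event and covariates must agree in length")
  df <- data.frame(patient_id = if (is.null(patient_id))
    sprintf("p%03d", seq_along(time)) else patient_id,
    time = time, event = as.integer(event))
  df <- cbind(df, as.data.frame(x))
  structure(df, class = c("survival_records", "data.frame"),
            covariates = colnames(x))
}

.rec_parts <- function(records) {
  stopifnot(inherits(records, "survival_records"))
  cov <- attr(records, "covariates")
  list(time = records$time, event = records$event,
       X = as.matrix(records[, cov, drop = FALSE]), covariates = cov)
}

#' Negative log partial likelihood of a Cox model
#'
#' \code{L(theta) = -sum_{i: E_i = 1} [theta' x_i - log sum_{j in R(t_i)}
#' exp(theta' x_j)]} with risk sets \code{R(t_i) = {j : T_j >= t_i}}
#' (Breslow convention: tied events and tied censored subjects stay in the
#' risk set), computed with log-sum-exp stabilization.
#'
#' @param theta Coefficient vector.
#' @param records A \code{\link{survival_records}} data.frame.
#' @return Scalar loss; 0 (with a warning) when no events are present.
#' @export
neg_log_partial_likelihood <- function(theta, records) {
  rp <- .rec_parts(records)
  if (!any(rp$event == 1L)) {
    warning("no events: partial likelihood is an empty sum")
    return(0)
  }
  lp <- as.vector(rp$X %*% theta)
  m <- max(lp)
  ev <- which(rp$event == 1L)
  s <- 0
  for (i in ev) {
    rs <- lp[rp$time >= rp$time[i]]
    s <- s + (lp[i] - (m + log(sum(exp(rs - m)))))
  }
  -s
}

# Gradient and Hessian of the negative log partial likelihood.
.cox_derivs <- function(theta, time, event, X) {
  lp <- as.vector(X %*% theta)
  w <- exp(lp - max(lp))
  p <- ncol(X)
  g <- numeric(p); Hm <- matrix(0, p, p)
  for (i in which(event == 1L)) {
    rs <- which(time >= time[i])
    wr <- w[rs]; sw <- sum(wr)
    xb <- colSums(X[rs, , drop = FALSE] * wr) / sw
    g <- g - (X[i, ] - xb)
    Xc <- sweep(X[rs, , drop = FALSE], 2, xb)
    Hm <- Hm + crossprod(Xc * sqrt(wr)) / sw
  }
  list(grad = g, hess = Hm)
}

#' Fit a Cox proportional-hazards model
#'
#' Minimizes the negative log partial likelihood (optionally with an L2
#' penalty) by Newton iterations with step-halving line search, then
#' estimates the baseline hazard with the Breslow method:
#' \code{h0(t_i) = d_i / sum_{j in R(t_i)} exp(theta' x_j)} at each distinct
#' event time.
#'
#' @param records A \code{\link{survival_records}} data.frame (>= 1 event).
#' @param l2 Ridge penalty on the coefficients (0 = none).
#' @param max_iter,tol Convergence controls on the gradient norm.
#' @return An object of class \code{wsimil_cox}: \code{coefficients},
#'   \code{vcov} (inverse observed information), \code{baseline}
#'   (data.frame time / hazard / cumhaz, nondecreasing cumulative),
#'   \code{loglik}, \code{iterations}, \code{converged},
#'   \code{gradient_norm}.
#' @export
cox_fit <- function(records, l2 = 0, max_iter = 50L, tol = 1e-8) {
  rp <- .rec_parts(records)
  if (!any(rp$event == 1L)) stop("cox_fit requires at least one event")
  p <- ncol(rp$X)
  theta <- numeric(p)
  nll <- function(th) neg_log_partial_likelihood(th, records) + l2 * sum(th^2) / 2
  f <- nll(theta)
  it <- 0L; gnorm <- Inf
  while (it < max_iter) {
    it <- it + 1L
    dv <- .cox_derivs(theta, rp$time, rp$event, rp$X)
    g <- dv$grad + l2 * theta
    Hm <- dv$hess + diag(l2, p)
    gnorm <- sqrt(sum(g^2))
    if (gnorm < tol) break
    step <- tryCatch(solve(Hm + diag(1e-10, p), g), error = function(e) g)
    alpha <- 1
    repeat {
      f_new <- nll(theta - alpha * step)
      if (is.finite(f_new) && f_new <= f + 1e-12) break
      alpha <- alpha / 2
      if (alpha < 1e-10) break
    }
    theta <- theta - alpha * step
    f <- nll(theta)
  }
  dv <- .cox_derivs(theta, rp$time, rp$event, rp$X)
  Hm <- dv$hess + diag(l2, p)
  vc <- tryCatch(solve(Hm), error = function(e) matrix(NA_real_, p, p))
  converged <- sqrt(sum((dv$grad + l2 * theta)^2)) < max(tol, 1e-6)
  if (!converged)
    warning(sprintf("Newton iterations did not converge: |grad| = %.3g after %d iterations",
                    sqrt(sum((dv$grad + l2 * theta)^2)), it))

  # Breslow baseline at distinct event times
  lp <- as.vector(rp$X %*% theta)
  evt <- sort(unique(rp$time[rp$event == 1L]))
  h0 <- vapply(evt, function(t0) {
    d <- sum(rp$event == 1L & rp$time == t0)
    d / sum(exp(lp[rp$time >= t0]))
  }, 0)
  baseline <- data.frame(time = evt, hazard = h0, cumhaz = cumsum(h0))

  names(theta) <- rp$covariates
  dimnames(vc) <- list(rp$covariates, rp$covariates)
  structure(list(coefficients = theta, vcov = vc, baseline = baseline,
                 loglik = -f, iterations = it, converged = converged,
                 gradient_norm = gnorm, n = nrow(records),
                 n_events = sum(rp$event), l2 = l2),
            class = "wsimil_cox")
}

#' @export
print.wsimil_cox <- function(x, ...) {
  cat(sprintf("<wsimil_cox> n = %d, events = %d | log partial likelihood %.4f (%s in %d iter)\n",
              x$n, x$n_events, x$loglik,
              if (x$converged) "converged" else "NOT converged", x$iterations))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' @export
coef.wsimil_cox <- function(object, ...) object$coefficients

#' @export
vcov.wsimil_cox <- function(object, ...) object$vcov

#' @export
summary.wsimil_cox <- function(object, ...) {
  se <- sqrt(diag(object$vcov))
  z <- object$coefficients / se
  tab <- data.frame(coef = object$coefficients, hr = exp(object$coefficients),
                    se = se, z = z, p = 2 * stats::pnorm(-abs(z)),
                    hr_lo95 = exp(object$coefficients - 1.96 * se),
                    hr_hi95 = exp(object$coefficients + 1.96 * se))
  rownames(tab) <- names(object$coefficients)
  out <- list(table = tab, n = object$n, n_events = object$n_events,
              loglik = object$loglik)
  class(out) <- "summary.wsimil_cox"
  out
}

#' @export
print.summary.wsimil_cox <- function(x, ...) {
  cat(sprintf("Cox proportional-hazards fit: n = %d, events = %d\n", x$n, x$n_events))
  print(round(x$table, 4))
  invisible(x)
}

#' @export
predict.wsimil_cox <- function(object, newdata, type = c("risk", "cumhaz"), ...) {
  type <- match.arg(type)
  X <- as.matrix(newdata)
  lp <- as.vector(X %*% object$coefficients)
  if (type == "risk") return(lp)
  function(t) {
    H0 <- stats::stepfun(object$baseline$time, c(0, object$baseline$cumhaz))(t)
    outer(exp(lp), H0)
  }
}

#' Linear-predictor risk score
#'
#' @param model A fitted \code{\link{cox_fit}} model.
#' @param x Covariate vector or matrix.
#' @return \code{theta' x} per row.
#' @export
risk_score <- function(model, x) {
  stopifnot(inherits(model, "wsimil_cox"))
  x <- rbind(x)
  if (ncol(x) != length(model$coefficients))
    stop(sprintf("covariate dimension %d does not match model dimension %d",
                 ncol(x), length(model$coefficients)))
  as.vector(x %*% model$coefficients)
}

#' Stratify patients into high/low risk groups
#'
#' Median split by default: scores strictly above the cutpoint are
#' high-risk; ties at the cutpoint go to the low-risk group.
#'
#' @param scores Risk scores (>= 2 values, not all equal).
#' @param cutpoint Cut value; defaults to the median of \code{scores}
#'   (pass the training-split median to stratify held-out patients).
#' @return Factor with levels \code{low}, \code{high}; the cutpoint is
#'   attached as attribute \code{"cutpoint"}.
#' @export
stratify <- function(scores, cutpoint = NULL) {
  if (length(scores) < 2L) stop("stratification requires at least 2 patients")
  if (max(scores) - min(scores) < 1e-12)
    stop("degenerate stratification: all risk scores are equal")
  if (is.null(cutpoint)) cutpoint <- stats::median(scores)
  g <- factor(ifelse(scores > cutpoint, "high", "low"), levels = c("low", "high"))
  attr(g, "cutpoint") <- cutpoint
  g
}

#' Univariate Cox regression: hazard ratio with Wald 95\% CI
#'
#' @param records A \code{\link{survival_records}} data.frame with a single
#'   covariate.
#' @return data.frame with hr, lo95, hi95, coef, se, z, p.
#' @export
univariate_hr <- function(records) {
  rp <- .rec_parts(records)
  if (ncol(rp$X) != 1L) stop("univariate_hr requires exactly one covariate")
  if (!any(rp$event == 1L)) stop("univariate_hr requires at least one event")
  fit <- cox_fit(records)
  s <- summary(fit)$table
  data.frame(hr = s$hr, lo95 = s$hr_lo95, hi95 = s$hr_hi95,
             coef = s$coef, se = s$se, z = s$z, p = s$p,
             row.names = rownames(s))
}
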