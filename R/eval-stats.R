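#' Pearson correlation with two-sided p-value
#'
#' Sample Pearson r and the two-sided p-value from the t-transform with
#' n - 2 degrees of freedom.
#'
#' @param x,y Numeric vectors (n >= 3, nonzero variance).
#' @return List with \code{r} and \code{p}.
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("pearson requires n >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("pearson is undefined for zero-variance input")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Benjamini-Hochberg adjustment with rejection set
#'
#' Step-up BH adjusted p-values (monotone, clipped at 1) and the rejections
#' at level \code{alpha} (\code{p_adj <= alpha}).
#'
#' @param pvals p-values in (0, 1].
#' @param alpha FDR level.
#' @return List with \code{p_adj}, logical \code{reject}, and \code{alpha}.
#' @export
bh_adjust <- function(pvals, alpha = 0.05) {
  if (!length(pvals)) return(list(p_adj = numeric(0), reject = logical(0), alpha = alpha))
  if (any(pvals <= 0 | pvals > 1)) stop("p-values must lie in (0, 1]")
  p_adj <- stats::p.adjust(pvals, method = "BH")
  list(p_adj = p_adj, reject = p_adj <= alpha, alpha = alpha)
}

#' ROC AUC via the rank (Mann-Whitney) formulation
#'
#' Ties contribute 1/2.
#'
#' @param scores Numeric prediction scores (higher = more positive).
#' @param labels Binary labels (both classes present).
#' @return Scalar AUC.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(scores) != length(labels)) stop("scores and labels must agree in length")
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop("roc_auc requires both classes")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Confusion matrix and accuracy for binary predictions
#'
#' @param pred,truth Binary vectors of equal length.
#' @return List with the 2 x 2 \code{matrix} (rows = truth, cols =
#'   prediction) and \code{accuracy}.
#' @export
confusion_and_accuracy <- function(pred, truth) {
  if (length(pred) != length(truth)) stop("pred and truth must agree in length")
  pred <- as.integer(pred); truth <- as.integer(truth)
  m <- matrix(c(sum(truth == 0 & pred == 0), sum(truth == 0 & pred == 1),
                sum(truth == 1 & pred == 0), sum(truth == 1 & pred == 1)),
              2, 2, byrow = TRUE,
              dimnames = list(truth = c("0", "1"), pred = c("0", "1")))
  list(matrix = m, accuracy = (m[1, 1] + m[2, 2]) / length(pred))
}

#' Harrell's concordance index
#'
#' Fraction of admissible pairs (the earlier-time member has an event) in
#' which the shorter-lived patient has the higher risk score; score ties
#' count 1/2.
#'
#' @param scores Risk scores (higher = worse predicted outcome).
#' @param records A \code{\link{survival_records}} data.frame.
#' @return Scalar C-index.
#' @export
c_index <- function(scores, records) {
  rp <- .rec_parts(records)
  n <- length(scores)
  stopifnot(n == nrow(records))
  conc <- 0; total <- 0
  for (i in seq_len(n)) {
    if (rp$event[i] != 1L) next
    comp <- which(rp$time > rp$time[i] |
                  (rp$time == rp$time[i] & rp$event == 0L))
    if (!length(comp)) next
    total <- total + length(comp)
    conc <- conc + sum(scores[i] > scores[comp]) + 0.5 * sum(scores[i] == scores[comp])
  }
  if (total == 0) stop("no comparable pairs for the concordance index")
  conc / total
}

#' Seeded patient-level k-fold assignment
#'
#' Folds are assigned at the patient level so that all slides of a patient
#' share a fold (no leakage); fold sizes differ by at most one.
#'
#' @param patient_ids Character vector of patient ids (one entry per slide
#'   is fine; duplicates map to the same fold).
#' @param k Number of folds (2 <= k <= number of distinct patients).
#' @param seed Seed for the permutation.
#' @return Integer fold labels (1..k) per input entry; the per-patient map
#'   is attached as attribute \code{"patient_fold"}.
#' @export
kfold <- function(patient_ids, k, seed = 1L) {
  pts <- unique(patient_ids)
  k <- as.integer(k)
  if (k < 2L) stop("k must be at least 2")
  if (k > length(pts)) stop("k exceeds the number of distinct patients")
  set.seed(derive_seed(seed, 7L))
  perm <- sample(pts)
  fold_of <- stats::setNames(rep(seq_len(k), length.out = length(pts)), perm)
  out <- unname(fold_of[as.character(patient_ids)])
  attr(out, "patient_fold") <- fold_of
  out
}
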