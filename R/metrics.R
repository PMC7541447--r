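# Evaluation metrics: coefficient of determination, mean absolute error,
# area under the ROC curve (Mann-Whitney formulation) and under the
# precision-recall curve (step interpolation).

#' Regression and classification metrics
#'
#' @param truth Numeric vector of observed values (or 0/1 labels for the
#'   classification metrics).
#' @param estimate Numeric vector of predictions (scores/probabilities for
#'   classification).
#' @return A single number.
#' @name metrics
NULL

#' @rdname metrics
#' @export
r_squared <- function(truth, estimate) {
  1 - sum((truth - estimate)^2) / sum((truth - mean(truth))^2)
}

#' @rdname metrics
#' @export
mae <- function(truth, estimate) mean(abs(truth - estimate))

#' @rdname metrics
#' @export
auroc <- function(truth, estimate) {
  truth <- as.integer(truth > 0)
  n1 <- sum(truth == 1); n0 <- sum(truth == 0)
  if (n1 == 0 || n0 == 0) stop("AUROC needs both classes", call. = FALSE)
  r <- rank(estimate, ties.method = "average")
  (sum(r[truth == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' @rdname metrics
#' @export
auprc <- function(truth, estimate) {
  truth <- as.integer(truth > 0)
  if (sum(truth) == 0) stop("AUPRC needs positive examples", call. = FALSE)
  ord <- order(estimate, decreasing = TRUE)
  y <- truth[ord]
  tp <- cumsum(y)
  precision <- tp / seq_along(y)
  recall <- tp / sum(y)
  # step integration over recall increments (average precision)
  sum(precision[y == 1]) / sum(y)
}
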