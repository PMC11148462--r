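# Ranking metrics for pair scoring.

#' Area under the ROC curve (midrank convention for ties)
#'
#' Computed from the rank statistic: `AUC = (sum of positive ranks -
#' P(P+1)/2) / (P * N)`, equivalent to the Wilcoxon-Mann-Whitney statistic
#' with ties counted one half.
#'
#' @param scores numeric scores
#' @param labels 0/1 labels
#' @return AUC in `[0, 1]`
#' @export
auc_roc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)),
            all(is.finite(scores)))
  P <- sum(labels == 1); N <- sum(labels == 0)
  if (P == 0 || N == 0) stop("AUC needs both classes present")
  r <- rank(scores)  # midranks for ties
  (sum(r[labels == 1]) - P * (P + 1) / 2) / (P * N)
}

#' Area under the precision-recall curve (step-function integration)
#'
#' Scores are sorted in decreasing order (stable, so tied scores keep
#' input order) and the step-wise average precision is accumulated at each
#' positive: `AUPR = sum_k (R_k - R_{k-1}) * P_k`.
#'
#' @param scores numeric scores
#' @param labels 0/1 labels
#' @return AUPR in `[0, 1]`
#' @export
aupr <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)),
            all(is.finite(scores)))
  P <- sum(labels == 1)
  if (P == 0 || sum(labels == 0) == 0) stop("AUPR needs both classes present")
  y <- labels[order(scores, decreasing = TRUE)]
  tp <- cumsum(y)
  prec <- tp / seq_along(y)
  sum(prec[y == 1]) / P
}

#' Evaluate a trained model on a labeled pair set
#'
#' @param model an `sl_model` from [train_sl_model()]
#' @param pairs an `sl_pairs` object containing both classes
#' @param kg optional `kg`; defaults to the propagation KG stored in the
#'   model
#' @return list of class `sl_metrics` with `auc_roc`, `aupr`, `n_pairs`
#' @export
evaluate_sl_model <- function(model, pairs, kg = NULL) {
  lab <- pairs$pairs$label
  if (length(unique(lab)) < 2L) stop("evaluation pairs must contain both classes")
  s <- predict_sl_model(model, pairs, kg = kg)
  structure(list(auc_roc = auc_roc(s, lab), aupr = aupr(s, lab),
                 n_pairs = length(s)), class = "sl_metrics")
}

#' @export
print.sl_metrics <- function(x, ...) {
  cat(sprintf("AUC-ROC %.4f | AUPR %.4f | %d pairs\n", x$auc_roc, x$aupr,
              x$n_pairs))
  invisible(x)
}
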