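#' Binary cross-entropy loss
#' @param y_true 0/1 labels.
#' @param y_prob predicted probabilities.
#' @param eps clipping bound to keep the loss finite.
#' @return mean BCE.
#' @export
bce_loss <- function(y_true, y_prob, eps = 1e-12) {
  p <- pmin(pmax(y_prob, eps), 1 - eps)
  -mean(y_true * log(p) + (1 - y_true) * log(1 - p))
}

#' Area under the ROC curve (rank method)
#'
#' Mann-Whitney formulation: the probability a random positive is scored
#' above a random negative, with half credit for ties.
#'
#' @param y_true 0/1 labels (both classes present).
#' @param y_prob scores.
#' @return AUC in `[0, 1]`.
#' @export
auc_score <- function(y_true, y_prob) {
  stopifnot(length(y_true) == length(y_prob))
  npos <- sum(y_true == 1); nneg <- sum(y_true == 0)
  if (npos == 0 || nneg == 0)
    stop("AUC undefined: both classes must be present")
  r <- rank(y_prob)  # midranks give 0.5 credit for ties
  (sum(r[y_true == 1]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' Classification metrics for the mortality model
#'
#' AUC by the rank/pair method, F1 at probability threshold 0.5, BCE loss,
#' and full ROC / precision-recall point sets over all unique score
#' thresholds.
#'
#' @inheritParams auc_score
#' @return list with `auc`, `f1`, `loss`, `roc` (data.frame fpr/tpr/
#'   threshold) and `pr` (data.frame recall/precision/threshold).
#' @examples
#' compute_metrics(c(0, 0, 1, 1), c(0.1, 0.4, 0.35, 0.8))$auc  # 0.75
#' @export
compute_metrics <- function(y_true, y_prob) {
  stopifnot(length(y_true) == length(y_prob), length(y_true) >= 1)
  y_true <- as.integer(y_true)
  single_class <- length(unique(y_true)) < 2L
  auc <- if (single_class) {
    warning("AUC undefined with single-class labels; returning NA")
    NA_real_
  } else auc_score(y_true, y_prob)

  pred <- as.integer(y_prob >= 0.5)
  tp <- sum(pred == 1 & y_true == 1)
  fp <- sum(pred == 1 & y_true == 0)
  fn <- sum(pred == 0 & y_true == 1)
  f1 <- if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)

  ord <- order(y_prob, decreasing = TRUE)
  ys <- y_true[ord]; ps <- y_prob[ord]
  cum_tp <- cumsum(ys == 1); cum_fp <- cumsum(ys == 0)
  last <- !duplicated(ps, fromLast = TRUE)  # one point per unique threshold
  npos <- sum(y_true == 1); nneg <- sum(y_true == 0)
  roc <- data.frame(
    fpr = c(0, cum_fp[last] / max(nneg, 1)),
    tpr = c(0, cum_tp[last] / max(npos, 1)),
    threshold = c(Inf, ps[last]))
  pr <- data.frame(
    recall = cum_tp[last] / max(npos, 1),
    precision = cum_tp[last] / (cum_tp[last] + cum_fp[last]),
    threshold = ps[last])
  list(auc = auc, f1 = f1, loss = bce_loss(y_true, y_prob),
       roc = roc, pr = pr)
}
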