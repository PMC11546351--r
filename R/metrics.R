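## Classification metrics: AUROC by pairwise concordance, AUPRC by
## precision-recall step integration, and threshold metrics at the optimal
## F1 cutoff.

#' Area under the ROC curve
#'
#' Computed as the pairwise concordance probability (Mann--Whitney statistic):
#' ties between a positive and a negative score receive 0.5 credit.
#'
#' @param scores numeric prediction scores
#' @param labels binary 0/1 labels
#' @return AUROC in [0, 1]
#' @export
auroc <- function(scores, labels) {
  labels <- as.integer(labels)
  n_pos <- sum(labels == 1L); n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L)
    stop("auroc: both classes must be present")
  r <- rank(scores)
  (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Area under the precision-recall curve
#'
#' Step integration of the precision-recall curve over distinct score
#' thresholds: AUPRC = sum over steps of (R_k - R_{k-1}) * P_k, with the
#' curve traversed from the highest threshold down.
#'
#' @inheritParams auroc
#' @return AUPRC in [0, 1]
#' @export
auprc <- function(scores, labels) {
  labels <- as.integer(labels)
  n_pos <- sum(labels == 1L)
  if (n_pos == 0L) stop("auprc: no positive samples")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- labels[o]
  tp <- cumsum(y); fp <- cumsum(1L - y)
  keep <- c(s[-1] != s[-length(s)], TRUE)   # last index of each tie group
  tp <- tp[keep]; fp <- fp[keep]
  prec <- tp / (tp + fp)
  rec <- tp / n_pos
  sum(diff(c(0, rec)) * prec)
}

#' Classification threshold maximizing F1
#'
#' Scans the distinct scores as candidate cutoffs (predicting positive when
#' score >= cutoff) and returns the one with the highest F1; ties go to the
#' larger cutoff.
#'
#' @inheritParams auroc
#' @return numeric threshold
#' @export
optimal_f1_threshold <- function(scores, labels) {
  labels <- as.integer(labels)
  cand <- sort(unique(scores), decreasing = TRUE)
  best_f1 <- -1; best_t <- cand[1L]
  for (t in cand) {
    pred <- scores >= t
    tp <- sum(pred & labels == 1L)
    f1 <- if (tp == 0L) 0 else 2 * tp / (sum(pred) + sum(labels == 1L))
    if (f1 > best_f1) { best_f1 <- f1; best_t <- t }
  }
  best_t
}

#' Evaluation report at the optimal-F1 threshold
#'
#' AUROC, AUPRC, and threshold metrics (accuracy, sensitivity, specificity)
#' at a fixed cutoff. If no threshold is supplied it is chosen by optimal F1
#' on the same scores; when reporting test performance, pass the threshold
#' frozen on the validation set to avoid leakage.
#'
#' @inheritParams auroc
#' @param threshold fixed classification cutoff, or \code{NULL} to derive it
#'   from these scores
#' @return object of class \code{dti_eval} with fields \code{auroc},
#'   \code{auprc}, \code{accuracy}, \code{sensitivity}, \code{specificity},
#'   \code{threshold}, \code{n_pos}, \code{n_neg}
#' @export
eval_report <- function(scores, labels, threshold = NULL) {
  labels <- as.integer(labels)
  if (is.null(threshold)) threshold <- optimal_f1_threshold(scores, labels)
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1L & labels == 1L); tn <- sum(pred == 0L & labels == 0L)
  fp <- sum(pred == 1L & labels == 0L); fn <- sum(pred == 0L & labels == 1L)
  structure(list(auroc = auroc(scores, labels),
                 auprc = auprc(scores, labels),
                 accuracy = (tp + tn) / length(labels),
                 sensitivity = if (tp + fn > 0L) tp / (tp + fn) else NA_real_,
                 specificity = if (tn + fp > 0L) tn / (tn + fp) else NA_real_,
                 threshold = threshold,
                 n_pos = sum(labels == 1L), n_neg = sum(labels == 0L)),
            class = "dti_eval")
}

#' @export
print.dti_eval <- function(x, ...) {
  cat(sprintf("AUROC %.4f | AUPRC %.4f | acc %.4f | sens %.4f | spec %.4f (threshold %.4f; %d pos / %d neg)\n",
              x$auroc, x$auprc, x$accuracy, x$sensitivity, x$specificity,
              x$threshold, x$n_pos, x$n_neg))
  invisible(x)
}

#' Binary cross-entropy loss with L2 regularization
#'
#' \code{L = -sum(y log p + (1 - y) log(1 - p)) + lambda/2 * sum(theta^2)}.
#' Probabilities outside (0, 1) are clamped to [1e-7, 1 - 1e-7] with a
#' warning.
#'
#' @param p predicted probabilities
#' @param y binary labels
#' @param lambda L2 weight
#' @param params optional list of parameter matrices entering the L2 term
#' @return scalar loss
#' @export
dti_loss <- function(p, y, lambda = 0, params = NULL) {
  eps <- 1e-7
  if (any(p <= 0 | p >= 1)) {
    warning("dti_loss: probabilities clamped to (0, 1)")
    p <- pmin(pmax(p, eps), 1 - eps)
  }
  ce <- -sum(y * log(p) + (1 - y) * log(1 - p))
  l2 <- if (!is.null(params) && lambda > 0)
    lambda / 2 * sum(vapply(params, function(w) sum(w^2), numeric(1))) else 0
  ce + l2
}
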