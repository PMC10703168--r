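#' Binary classification metrics from predicted scores
#'
#' Computes the confusion matrix at a decision threshold and the standard
#' derived metrics, plus the threshold-free AUC as the Mann-Whitney rank
#' statistic (the probability that a random positive outscores a random
#' negative, ties counting one half).
#'
#' Precision is reported as 0 (with attribute `precision_undefined = TRUE`)
#' when no sample is predicted positive, so averages over repeated evaluations
#' stay defined; F1 is likewise 0 when its denominator vanishes.
#'
#' @param labels Integer 0/1 vector of true classes (both classes required).
#' @param scores Numeric vector of predicted class-1 probabilities in
#'   \eqn{[0, 1]}.
#' @param threshold Decision threshold: predicted class is
#'   `score >= threshold`. Default 0.5.
#' @return A named list (class `metric_set`): `accuracy`, `sensitivity`,
#'   `specificity`, `precision`, `f1`, `auc`, and `confusion` (named integer
#'   vector TP, FP, TN, FN).
#' @export
compute_metrics <- function(labels, scores, threshold = 0.5) {
  labels <- as.integer(labels)
  stopifnot(length(labels) == length(scores),
            all(labels %in% c(0L, 1L)),
            all(scores >= 0 & scores <= 1))
  if (length(unique(labels)) < 2L)
    stop("labels contain a single class; AUC is undefined")
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1L & labels == 1L)
  fp <- sum(pred == 1L & labels == 0L)
  tn <- sum(pred == 0L & labels == 0L)
  fn <- sum(pred == 0L & labels == 1L)
  npos <- tp + fn
  nneg <- tn + fp
  sens <- tp / npos
  spec <- tn / nneg
  prec_undef <- (tp + fp) == 0L
  prec <- if (prec_undef) 0 else tp / (tp + fp)
  f1 <- if (prec + sens > 0) 2 * prec * sens / (prec + sens) else 0
  # Mann-Whitney AUC via midranks; ties contribute 1/2 automatically
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[labels == 1L]) - npos * (npos + 1) / 2) / (npos * nneg)
  out <- list(accuracy = (tp + tn) / length(labels),
              sensitivity = sens, specificity = spec,
              precision = prec, f1 = f1, auc = auc,
              confusion = c(TP = tp, FP = fp, TN = tn, FN = fn))
  if (prec_undef) attr(out, "precision_undefined") <- TRUE
  class(out) <- "metric_set"
  out
}

#' @export
print.metric_set <- function(x, ...) {
  cat(sprintf("acc %.3f  sens %.3f  spec %.3f  prec %.3f  f1 %.3f  auc %.3f\n",
              x$accuracy, x$sensitivity, x$specificity, x$precision, x$f1,
              x$auc))
  invisible(x)
}

# Flatten a metric_set into a named numeric vector (confusion included).
metric_row <- function(m) {
  c(accuracy = m$accuracy, sensitivity = m$sensitivity,
    specificity = m$specificity, precision = m$precision, f1 = m$f1,
    auc = m$auc, m$confusion)
}
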