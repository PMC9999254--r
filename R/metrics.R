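# Evaluation metrics for the imbalanced HAPI task: area under the ROC curve
# (rank statistic, tie-aware) and area under the precision-recall curve
# (average precision), plus the paired one-sided t test used to compare
# definitions across test sets.

#' Area under the ROC curve
#'
#' Computed from the Mann-Whitney rank statistic with midranks for ties.
#'
#' @param scores numeric classifier scores.
#' @param labels 0/1 (or logical) true labels.
#' @return AUROC in \[0, 1\].
#' @export
auroc <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("auroc needs both classes", call. = FALSE)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve (average precision)
#'
#' The step-interpolated average precision: sum over descending score
#' thresholds of the recall increment times the precision at that threshold.
#'
#' @inheritParams auroc
#' @return AUPRC in \[0, 1\].
#' @export
auprc <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  n_pos <- sum(labels == 1)
  if (n_pos == 0 || n_pos == length(labels)) stop("auprc needs both classes", call. = FALSE)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  tp <- cumsum(y); fp <- cumsum(1 - y)
  # threshold at each distinct score (last index of each tie group)
  last <- which(!duplicated(s, fromLast = TRUE))
  tp <- tp[last]; fp <- fp[last]
  precision <- tp / (tp + fp)
  recall <- tp / n_pos
  sum(diff(c(0, recall)) * precision)
}

#' One-sided paired t test between two metric vectors
#'
#' Tests whether `mean(a - b) > 0`, pairing by test-set index. Degenerate
#' inputs are flagged rather than erroring: identical vectors give p = 0.5,
#' a constant nonzero difference gives p = 0.
#'
#' @param scores_a,scores_b equal-length metric vectors (length >= 2).
#' @return list with `p_value`, `t`, `df`, `mean_diff`, `degenerate`.
#' @export
paired_onesided_ttest <- function(scores_a, scores_b) {
  if (length(scores_a) != length(scores_b))
    stop("paired test needs equal-length vectors", call. = FALSE)
  if (length(scores_a) < 2) stop("need at least 2 paired observations", call. = FALSE)
  d <- scores_a - scores_b
  if (stats::sd(d) == 0) {
    if (all(d == 0))
      return(list(p_value = 0.5, t = NA_real_, df = length(d) - 1,
                  mean_diff = 0, degenerate = TRUE))
    return(list(p_value = if (mean(d) > 0) 0 else 1, t = NA_real_,
                df = length(d) - 1, mean_diff = mean(d), degenerate = TRUE))
  }
  tt <- stats::t.test(scores_a, scores_b, paired = TRUE, alternative = "greater")
  list(p_value = unname(tt$p.value), t = unname(tt$statistic),
       df = unname(tt$parameter), mean_diff = unname(mean(d)), degenerate = FALSE)
}
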