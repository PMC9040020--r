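# Classification metrics and interval overlap rates.

#' Area under the ROC curve
#'
#' Computed via the Mann-Whitney U statistic with ties counted one half,
#' which is exactly the probability that a random positive outranks a
#' random negative (and equals the trapezoidal area under the ROC
#' curve).
#'
#' @param scores numeric prediction scores.
#' @param labels 0/1 labels.
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), all(is.finite(scores)),
            all(labels %in% c(0, 1)))
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0) stop("both classes required for AUROC")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Area under the precision-recall curve
#'
#' Computed as average precision: the sum over score thresholds of the
#' precision at that threshold weighted by the recall increment (no
#' linear interpolation between points, so tied scores are handled as a
#' block). Equals 1 for a perfect ranking and approaches the positive
#' prevalence for uninformative scores.
#'
#' @inheritParams auroc
#' @return AUPRC in `[0, 1]`.
#' @export
auprc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), all(is.finite(scores)),
            all(labels %in% c(0, 1)))
  n_pos <- sum(labels == 1)
  if (n_pos == 0) stop("at least one positive required for AUPRC")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- labels[ord]
  tp <- cumsum(y)
  fp <- cumsum(1 - y)
  # evaluate at the last index of each tied-score block
  keep <- c(s[-1] != s[-length(s)], TRUE)
  tp <- tp[keep]; fp <- fp[keep]
  precision <- tp / (tp + fp)
  recall <- tp / n_pos
  sum(diff(c(0, recall)) * precision)
}

#' Fraction of intervals in one set overlapping another
#'
#' An interval of `a` counts as overlapping if it shares at least one
#' base with any interval of `b`.
#'
#' @param a,b interval data frames (0-based half-open).
#' @return Fraction of `a` intervals overlapped, in `[0, 1]`.
#' @export
overlap_rate <- function(a, b) {
  validate_intervals(a)
  if (nrow(a) == 0) stop("first interval set is empty")
  if (nrow(b) == 0) return(0)
  validate_intervals(b)
  hits <- GenomicRanges::countOverlaps(iv_to_granges(a), iv_to_granges(b))
  mean(hits > 0)
}
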