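# Threshold-free ranking metrics (AUROC, AUPR) and thresholded confusion
# statistics (F1, MCC) for link prediction.

#' Area under the ROC curve
#'
#' Rank statistic over all positive-negative pairs; ties count one half.
#' @param labels 0/1 vector.
#' @param scores numeric scores, same length.
#' @export
auroc <- function(labels, scores) {
  check_two_class(labels)
  r <- rank(scores)
  n_pos <- sum(labels == 1); n_neg <- sum(labels == 0)
  (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Area under the precision-recall curve
#'
#' Step integration of precision over recall along the score-sorted list
#' (ties kept in input order), i.e. average precision.
#' @inheritParams auroc
#' @export
aupr <- function(labels, scores) {
  check_two_class(labels)
  ord <- order(scores, decreasing = TRUE)
  y <- labels[ord]
  tp <- cumsum(y)
  precision <- tp / seq_along(y)
  sum(precision[y == 1]) / sum(y)
}

confusion <- function(labels, scores, threshold) {
  pred <- as.numeric(scores >= threshold)
  c(tp = sum(pred == 1 & labels == 1), fp = sum(pred == 1 & labels == 0),
    fn = sum(pred == 0 & labels == 1), tn = sum(pred == 0 & labels == 0))
}

#' F1 score at a threshold
#' @inheritParams auroc
#' @param threshold score cutoff (default 0.5).
#' @export
f1_score <- function(labels, scores, threshold = 0.5) {
  check_two_class(labels)
  cm <- confusion(labels, scores, threshold)
  denom <- 2 * cm["tp"] + cm["fp"] + cm["fn"]
  if (denom == 0) return(0)
  unname(2 * cm["tp"] / denom)
}

#' Matthews correlation coefficient at a threshold
#' @inheritParams f1_score
#' @export
mcc <- function(labels, scores, threshold = 0.5) {
  check_two_class(labels)
  cm <- confusion(labels, scores, threshold)
  denom <- sqrt(prod(c(cm["tp"] + cm["fp"], cm["tp"] + cm["fn"],
                       cm["tn"] + cm["fp"], cm["tn"] + cm["fn"])))
  if (denom == 0) return(0)
  unname((cm["tp"] * cm["tn"] - cm["fp"] * cm["fn"]) / denom)
}

check_two_class <- function(labels) {
  if (!all(labels %in% c(0, 1))) stopf("labels must be 0/1")
  if (length(unique(labels)) < 2) {
    stopf("metric undefined: test set contains a single class")
  }
  invisible(TRUE)
}

#' Compute the full metric set for a scored test set
#'
#' @inheritParams f1_score
#' @return list with `auroc`, `aupr`, `f1`, `mcc`, `threshold`, plus
#'   `best_f1` and `best_f1_threshold` (the score grid maximizer).
#' @export
metric_set <- function(labels, scores, threshold = 0.5) {
  grid <- sort(unique(scores))
  f1s <- vapply(grid, function(t) f1_score(labels, scores, t), numeric(1))
  best <- which.max(f1s)
  list(auroc = auroc(labels, scores), aupr = aupr(labels, scores),
       f1 = f1_score(labels, scores, threshold),
       mcc = mcc(labels, scores, threshold), threshold = threshold,
       best_f1 = f1s[best], best_f1_threshold = grid[best])
}
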