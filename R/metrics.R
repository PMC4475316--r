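#' Binary classification metrics with UN as the positive class
#'
#' Sensitivity is the proportion of UN records classified UN; specificity
#' the proportion of AC records classified AC. When a class is absent from
#' the truth the corresponding rate is `NaN`.
#'
#' @param predicted character vector of `"AC"`/`"UN"` labels.
#' @param truth reference labels, same length.
#' @return An object of class `ecg_eval`: list with `accuracy`,
#'   `sensitivity`, `specificity`, confusion counts `tp`, `tn`, `fp`, `fn`
#'   and `n`.
#' @export
evaluate_labels <- function(predicted, truth) {
  predicted <- as.character(predicted); truth <- as.character(truth)
  if (length(predicted) != length(truth))
    stop_input("evaluate_labels: %d predictions vs %d truth labels",
               length(predicted), length(truth))
  if (length(truth) < 1L)
    stop_input("evaluate_labels: empty label vectors")
  bad <- setdiff(c(predicted, truth), c("AC", "UN"))
  if (length(bad))
    stop_input("evaluate_labels: illegal label(s): %s", paste(unique(bad), collapse = ", "))
  tp <- sum(predicted == "UN" & truth == "UN")
  tn <- sum(predicted == "AC" & truth == "AC")
  fp <- sum(predicted == "UN" & truth == "AC")
  fn <- sum(predicted == "AC" & truth == "UN")
  n <- length(truth)
  structure(list(
    accuracy = (tp + tn) / n,
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NaN,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NaN,
    tp = tp, tn = tn, fp = fp, fn = fn, n = n), class = "ecg_eval")
}

#' @export
print.ecg_eval <- function(x, ...) {
  cat(sprintf("accuracy %.3f | sensitivity %.3f | specificity %.3f (n = %d)\n",
              x$accuracy, x$sensitivity, x$specificity, x$n))
  cat(sprintf("  TP %d  FN %d  FP %d  TN %d  (positive class: UN)\n",
              x$tp, x$fn, x$fp, x$tn))
  invisible(x)
}

# Rank-based AUC (midranks for ties); UN is the positive class.
auc_from_scores <- function(scores, truth) {
  pos <- truth == "UN"
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) return(NaN)
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
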