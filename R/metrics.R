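#' Confusion matrix and the classification metric suite
#'
#' Threshold metrics from the user-level confusion matrix (balanced
#' accuracy, sensitivity, specificity, precision, recall, F1, macro F1) plus
#' ranking metrics (AUC via the rank/Mann-Whitney statistic, AUC-PR by
#' precision-recall step integration).
#'
#' @param labels Logical vector of true user labels.
#' @param probabilities Predicted user-level probabilities.
#' @param threshold Decision threshold on the averaged probability.
#' @return List with `confusion` (tibble `tp`, `fp`, `tn`, `fn`) and
#'   `metrics` (one-row tibble).
#' @examples
#' confusion_and_metrics(c(TRUE, FALSE), c(0.9, 0.1))$metrics
#' @export
confusion_and_metrics <- function(labels, probabilities, threshold = 0.5) {
  labels <- as.logical(labels)
  if (length(labels) != length(probabilities)) {
    stop_phenosense("labels and probabilities must have equal length.",
                    "phenosense_validation_error")
  }
  if (all(labels) || !any(labels)) {
    stop_phenosense(
      "Both classes must be present: threshold metrics are undefined and AUC does not exist for one-class truth.",
      "phenosense_validation_error"
    )
  }
  pred <- probabilities >= threshold
  tp <- sum(pred & labels); fp <- sum(pred & !labels)
  tn <- sum(!pred & !labels); fn <- sum(!pred & labels)
  metrics <- metrics_from_counts(tp, fp, tn, fn)
  metrics$auc <- auc_rank(labels, probabilities)
  metrics$auc_pr <- auc_pr(labels, probabilities)
  list(confusion = tibble(tp = tp, fp = fp, tn = tn, fn = fn),
       metrics = as_tibble(metrics[c(
         "balanced_accuracy", "auc", "auc_pr", "f1", "f1_macro",
         "sensitivity", "specificity", "precision", "recall")]))
}

#' Metrics from raw confusion counts
#'
#' @param tp,fp,tn,fn Confusion counts.
#' @return Named list of threshold metrics.
#' @examples
#' metrics_from_counts(tp = 15, fp = 13, tn = 33, fn = 6)$balanced_accuracy
#' @export
metrics_from_counts <- function(tp, fp, tn, fn) {
  sens <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  f1_pos <- 2 * tp / (2 * tp + fp + fn)
  f1_neg <- 2 * tn / (2 * tn + fn + fp)
  list(balanced_accuracy = (sens + spec) / 2,
       sensitivity = sens, specificity = spec, precision = prec,
       recall = sens, f1 = f1_pos, f1_macro = (f1_pos + f1_neg) / 2,
       accuracy = (tp + tn) / (tp + fp + tn + fn))
}

# AUC by the rank (Mann-Whitney) formulation, midranks for ties.
auc_rank <- function(labels, probabilities) {
  r <- rank(probabilities)
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

# Area under the precision-recall curve by step integration over descending
# score thresholds (average-precision form).
auc_pr <- function(labels, probabilities) {
  ord <- order(probabilities, decreasing = TRUE)
  y <- as.numeric(labels[ord])
  tp <- cumsum(y)
  prec <- tp / seq_along(y)
  rec <- tp / sum(y)
  prev_rec <- c(0, rec[-length(rec)])
  # average-precision step integral: precision at each recall increment
  sum((rec - prev_rec) * prec)
}

#' Exact Wilcoxon signed-rank test (paired, two-sided)
#'
#' Exact null enumeration over sign assignments via a dynamic program on
#' (doubled) midranks, valid under ties in the differences. Zero
#' differences are dropped; all-zero differences give p = 1.
#'
#' @param x,y Paired numeric vectors.
#' @return List with `statistic` (V, sum of positive-difference ranks) and
#'   `p_value`.
#' @export
wilcoxon_signed_rank_exact <- function(x, y) {
  if (length(x) != length(y)) {
    stop_phenosense("Paired vectors must have equal length.",
                    "phenosense_validation_error")
  }
  d <- x - y
  d <- d[d != 0]
  m <- length(d)
  if (m == 0L) return(list(statistic = 0, p_value = 1))
  r2 <- 2 * rank(abs(d))  # doubled midranks are integers
  v2 <- sum(r2[d > 0])
  # DP over achievable doubled-rank sums; counts[s + 1] = number of sign
  # assignments with positive-rank doubled-sum s
  total <- sum(r2)
  counts <- numeric(total + 1)
  counts[1] <- 1
  for (ri in r2) {
    shifted <- c(numeric(ri), counts[seq_len(total + 1 - ri)])
    counts <- counts + shifted
  }
  probs <- counts / 2^m
  sums <- 0:total
  p_low <- sum(probs[sums <= v2])
  p_high <- sum(probs[sums >= v2])
  list(statistic = v2 / 2, p_value = min(1, 2 * min(p_low, p_high)))
}

#' Compare two paired experiment runs
#'
#' Two-sided paired test on per-repetition balanced accuracies (or any
#' paired metric vectors): exact Wilcoxon signed-rank or paired t.
#'
#' @param result_a,result_b `loso_result` objects or numeric vectors of
#'   equal length.
#' @param test `"wilcoxon"` or `"paired_t"`.
#' @param metric Metric column extracted from `loso_result` objects.
#' @return Tibble with `test`, `statistic`, `p_value`, `mean_diff`.
#' @export
compare_runs <- function(result_a, result_b,
                         test = c("wilcoxon", "paired_t"),
                         metric = "balanced_accuracy") {
  test <- match.arg(test)
  get_vec <- function(r) {
    if (inherits(r, "loso_result")) r$rep_metrics[[metric]] else as.numeric(r)
  }
  a <- get_vec(result_a)
  b <- get_vec(result_b)
  if (length(a) != length(b)) {
    stop_phenosense("Paired metric vectors must have equal length.",
                    "phenosense_validation_error")
  }
  if (test == "wilcoxon") {
    w <- wilcoxon_signed_rank_exact(a, b)
    tibble(test = "wilcoxon", statistic = w$statistic, p_value = w$p_value,
           mean_diff = mean(a - b))
  } else {
    if (all(a == b)) {
      return(tibble(test = "paired_t", statistic = 0, p_value = 1,
                    mean_diff = 0))
    }
    tt <- t.test(a, b, paired = TRUE)
    tibble(test = "paired_t", statistic = unname(tt$statistic),
           p_value = tt$p.value, mean_diff = mean(a - b))
  }
}
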