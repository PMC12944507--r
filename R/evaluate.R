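## ---------------------------------------------------------------------------
## Evaluation primitives: stratified folds, screening metrics, rank AUC,
## threshold sweep, leave-one-subgroup-out fusion and the intermediate-AHI
## group. OSA is the positive class throughout.
## ---------------------------------------------------------------------------

#' Stratified k-fold partition
#'
#' Shuffles within class and deals round-robin, so per-fold class counts
#' differ from exact proportionality by at most one subject.
#'
#' @param labels class labels.
#' @param k number of folds.
#' @param seed integer seed.
#' @return list of `k` integer index vectors (a partition).
#' @export
stratified_folds <- function(labels, k, seed = 1L) {
  cls <- split(seq_along(labels), labels)
  if (any(lengths(cls) < k))
    stopf("class count below k = %d", k)
  set.seed(derive_seed(seed, "folds", k))
  folds <- vector("list", k)
  for (idx in cls) {
    idx <- sample(idx)
    f <- rep(seq_len(k), length.out = length(idx))
    for (j in seq_len(k)) folds[[j]] <- c(folds[[j]], idx[f == j])
  }
  lapply(folds, sort)
}

#' Inner cross-validation fold count
#'
#' `k = clamp(floor(n_minority / 3), 3, 6)`: more folds when the
#' subgroup's minority class can support them. Below 3 minority subjects
#' a single split is used (with a warning).
#'
#' @param n_minority_train minority-class training count in the subgroup.
#' @return integer in 3..6, or 1 (single split) with a warning.
#' @export
choose_inner_k <- function(n_minority_train) {
  if (n_minority_train < 3) {
    warning("fewer than 3 minority subjects; falling back to a single split")
    return(1L)
  }
  as.integer(min(max(floor(n_minority_train / 3), 3L), 6L))
}

#' Confusion matrix from labels
#'
#' @param truth true labels (`"OSA"` positive).
#' @param pred predicted labels.
#' @return list with `tp`, `tn`, `fp`, `fn`.
#' @export
confusion_counts <- function(truth, pred) {
  list(tp = sum(truth == LABEL_OSA & pred == LABEL_OSA),
       tn = sum(truth == LABEL_NON & pred == LABEL_NON),
       fp = sum(truth == LABEL_NON & pred == LABEL_OSA),
       fn = sum(truth == LABEL_OSA & pred == LABEL_NON))
}

#' Screening metrics from a confusion matrix
#'
#' Accuracy, sensitivity (recall on OSA), specificity and balanced
#' accuracy (their mean), as percentages. Metrics with an empty
#' denominator are `NA`.
#'
#' @param cm list with `tp`, `tn`, `fp`, `fn`.
#' @return list of percentages (unrounded; round half-up to one decimal
#'   for table-style reporting).
#' @export
compute_metrics <- function(cm) {
  total <- cm$tp + cm$tn + cm$fp + cm$fn
  if (total == 0) stopf("empty confusion matrix")
  npos <- cm$tp + cm$fn
  nneg <- cm$tn + cm$fp
  acc <- 100 * (cm$tp + cm$tn) / total
  sens <- if (npos > 0) 100 * cm$tp / npos else NA_real_
  spec <- if (nneg > 0) 100 * cm$tn / nneg else NA_real_
  bal <- if (!is.na(sens) && !is.na(spec)) (sens + spec) / 2 else NA_real_
  list(accuracy = acc, sensitivity = sens, specificity = spec,
       balanced_accuracy = bal)
}

#' Rank-based AUC
#'
#' Concordance probability estimator (Wilcoxon statistic) with half
#' credit for ties.
#'
#' @param probs predicted OSA probabilities.
#' @param labels true labels.
#' @return AUC in `[0, 1]`; `NA` if only one class present.
#' @export
auc_score <- function(probs, labels) {
  pos <- labels == LABEL_OSA
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(probs)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Threshold sweep
#'
#' Metrics across decision thresholds (default 0.40-0.60 in steps of
#' 0.01) applied to fused probabilities; a subject is labeled OSA when
#' `p >= threshold`.
#'
#' @param probs fused probabilities.
#' @param labels true labels.
#' @param grid thresholds.
#' @return data.frame: `threshold`, `accuracy`, `sensitivity`,
#'   `specificity`, `balanced_accuracy` (percent).
#' @export
threshold_sweep <- function(probs, labels, grid = seq(0.40, 0.60, by = 0.01)) {
  rows <- lapply(grid, function(t) {
    pred <- ifelse(probs >= t, LABEL_OSA, LABEL_NON)
    m <- compute_metrics(confusion_counts(labels, pred))
    data.frame(threshold = t, accuracy = m$accuracy,
               sensitivity = m$sensitivity, specificity = m$specificity,
               balanced_accuracy = m$balanced_accuracy)
  })
  do.call(rbind, rows)
}

#' Leave-one-subgroup-out fusion
#'
#' Recomputes the fused probability for every subject after removing one
#' sub-classifier from its relevant set, quantifying that subgroup's
#' contribution to the ensemble.
#'
#' @param prob_matrix subjects x subgroups matrix of OSA probabilities
#'   (`NA` where a subgroup is not relevant to a subject).
#' @param labels true labels.
#' @param exclude_id subgroup id (column) to remove.
#' @param threshold decision threshold.
#' @param on_empty what to do with subjects left without any
#'   sub-classifier after the exclusion (cannot happen when all nine are
#'   trainable): `"error"` or `"drop"` them from the row's metrics.
#' @return one-row data.frame of metrics after exclusion.
#' @export
loso_fusion <- function(prob_matrix, labels, exclude_id, threshold = 0.5,
                        on_empty = c("error", "drop")) {
  on_empty <- match.arg(on_empty)
  if (!exclude_id %in% colnames(prob_matrix))
    stopf("unknown subgroup id: %s", exclude_id)
  pm <- prob_matrix[, setdiff(colnames(prob_matrix), exclude_id), drop = FALSE]
  n_rel <- rowSums(!is.na(pm))
  if (any(n_rel == 0)) {
    if (on_empty == "error") stopf("a subject has no remaining sub-classifier")
    pm <- pm[n_rel > 0, , drop = FALSE]
    labels <- labels[n_rel > 0]
  }
  p_final <- rowMeans(pm, na.rm = TRUE)
  pred <- ifelse(p_final >= threshold, LABEL_OSA, LABEL_NON)
  m <- compute_metrics(confusion_counts(labels, pred))
  data.frame(excluded = exclude_id, balanced_accuracy = m$balanced_accuracy,
             accuracy = m$accuracy, sensitivity = m$sensitivity,
             specificity = m$specificity, auc = auc_score(p_final, labels),
             stringsAsFactors = FALSE)
}

#' Fraction of intermediate-AHI subjects classified as OSA
#'
#' @param p_final fused probabilities for the gap-group subjects.
#' @param threshold decision threshold.
#' @return fraction in `[0, 1]`.
#' @export
gap_fraction_osa <- function(p_final, threshold = 0.5) {
  if (length(p_final) == 0) return(NA_real_)
  mean(p_final >= threshold)
}
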