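## ---------------------------------------------------------------------------
## Two-level framework: per-subgroup inner cross-validation (stability
## feature selection + hyperparameter tuning), final sub-classifier
## training, dynamic-selection fusion, and the outer stratified 4-fold
## evaluation harness.
## ---------------------------------------------------------------------------

#' Framework configuration
#'
#' Defaults are the study settings: B = 1000 balanced subsets, 7 stable
#' acoustic features (+3 anthropometric), outer stratified 4-fold
#' cross-validation, inner repeated stratified k-fold (k in 3..6 by
#' minority count), decision threshold 0.5.
#'
#' @param B balanced subsets per stability selection.
#' @param k_features stable acoustic features per sub-classifier.
#' @param min_score greedy mRMR stop threshold.
#' @param outer_k outer folds.
#' @param inner_repeats repeats of the inner k-fold.
#' @param hyper_grid data.frame of tree hyperparameters (`maxdepth`,
#'   `minbucket`) searched by inner-validation balanced accuracy.
#' @param threshold fusion decision threshold.
#' @param mode fusion mode, `"probability"` or `"majority"`.
#' @return a `framework_config` list.
#' @export
framework_config <- function(B = 1000L, k_features = 7L, min_score = 0.01,
                             outer_k = 4L, inner_repeats = 5L,
                             hyper_grid = expand.grid(
                               maxdepth = c(3L, 5L, 30L),
                               minbucket = c(1L, 3L, 5L)),
                             threshold = 0.5,
                             mode = c("probability", "majority")) {
  structure(list(B = as.integer(B), k_features = as.integer(k_features),
                 min_score = min_score, outer_k = as.integer(outer_k),
                 inner_repeats = as.integer(inner_repeats),
                 hyper_grid = hyper_grid, threshold = threshold,
                 mode = match.arg(mode)),
            class = "framework_config")
}

## Inner loop of one subgroup: repeated stratified k-fold producing (a)
## one stability-selected candidate set per inner split and (b) pooled
## validation predictions per hyperparameter, then consensus features +
## best hyperparameters + final ensemble on all subgroup training data.
train_one_subgroup <- function(X, meta, subgroup_id, config, seed) {
  y <- meta$label
  tab <- table(factor(y, levels = c(LABEL_NON, LABEL_OSA)))
  if (any(tab < 2)) return(NULL)
  n_minority <- min(tab)
  k_inner <- suppressWarnings(choose_inner_k(n_minority))
  grid <- config$hyper_grid
  candidate_sets <- list()
  val_probs <- rep(list(numeric(0)), nrow(grid))
  val_truth <- character(0)

  for (r in seq_len(config$inner_repeats)) {
    folds <- if (k_inner >= 2) {
      stratified_folds(y, k_inner, derive_seed(seed, subgroup_id, "inner", r))
    } else {
      ## single stratified split: 2 folds, validate on the second only
      stratified_folds(y, 2L, derive_seed(seed, subgroup_id, "inner", r))[2]
    }
    for (j in seq_along(folds)) {
      val <- folds[[j]]
      tr <- setdiff(seq_along(y), val)
      if (length(unique(y[tr])) < 2 || length(unique(y[val])) < 1) next
      if (min(table(y[tr])) < 2) next
      ## class-swap warnings are routine in subgroups where non-OSA is
      ## not the minority
      st <- suppressWarnings(
        stability_select(X[tr, , drop = FALSE], y[tr], B = config$B,
                         k = config$k_features,
                         seed = derive_seed(seed, subgroup_id, "stab", r, j),
                         min_score = config$min_score))
      cand <- st$top_stable
      if (length(cand) == 0) next
      candidate_sets[[length(candidate_sets) + 1L]] <- cand
      fset <- assemble_final(cand)
      for (g in seq_len(nrow(grid))) {
        sc <- train_subclassifier(X[tr, , drop = FALSE], meta[tr, , drop = FALSE],
                                  fset, as.list(grid[g, ]), subgroup_id,
                                  seed = derive_seed(seed, subgroup_id, "tune", r, j, g))
        p <- subclassifier_proba(sc, X[val, , drop = FALSE],
                                 meta[val, , drop = FALSE])
        val_probs[[g]] <- c(val_probs[[g]], p)
      }
      val_truth <- c(val_truth, y[val])
    }
  }
  if (length(candidate_sets) == 0) return(NULL)

  bal_acc <- vapply(seq_len(nrow(grid)), function(g) {
    pred <- ifelse(val_probs[[g]] >= 0.5, LABEL_OSA, LABEL_NON)
    m <- compute_metrics(confusion_counts(val_truth, pred))
    if (is.na(m$balanced_accuracy)) -Inf else m$balanced_accuracy
  }, numeric(1))
  best <- which.max(bal_acc)

  final_features <- assemble_final(consensus_rank(candidate_sets, config$k_features))
  model <- train_subclassifier(X, meta, final_features,
                               as.list(grid[best, ]), subgroup_id,
                               seed = derive_seed(seed, subgroup_id, "final"))
  model$inner <- list(k_inner = k_inner, candidate_sets = candidate_sets,
                      grid_balanced_accuracy = bal_acc, best_grid = best)
  model
}

#' Train the two-level ensemble on a training population
#'
#' Fits the z-score scaler, then one sub-classifier per anthropometric
#' subgroup (inner repeated stratified k-fold for stability feature
#' selection and hyperparameter tuning, then a final balanced bagged
#' ensemble on the whole subgroup). Subgroups whose training data lack a
#' class are marked untrainable and excluded from fusion.
#'
#' @param X raw (unscaled) acoustic feature matrix, training subjects x 640.
#' @param meta training metadata (anthropometrics + `label`).
#' @param config a [framework_config()].
#' @param seed integer seed.
#' @return an `osa_model`.
#' @export
train_osa_model <- function(X, meta, config = framework_config(), seed = 1L) {
  stopifnot(nrow(X) == nrow(meta))
  keep <- stats::complete.cases(X)
  if (!all(keep)) {
    X <- X[keep, , drop = FALSE]         # subjects with missing maneuvers
    meta <- meta[keep, , drop = FALSE]   # are dropped from training
  }
  scaler <- zscore_fit(X)
  Xz <- zscore_apply(scaler, X)
  membership <- subgroup_membership(meta)
  subs <- stats::setNames(vector("list", length(subgroup_ids())), subgroup_ids())
  for (id in subgroup_ids()) {
    rows <- which(membership[, id])
    if (length(rows) < 4) next
    subs[[id]] <- train_one_subgroup(Xz[rows, , drop = FALSE],
                                     meta[rows, , drop = FALSE],
                                     id, config, seed)
  }
  structure(list(scaler = scaler, subclassifiers = subs, config = config,
                 seed = seed), class = "osa_model")
}

#' Predict with a trained two-level ensemble
#'
#' Applies the training z-scaler, queries every trainable sub-classifier
#' relevant to each subject (the set Kx) and fuses the probabilities.
#' Missing acoustic values (unavailable maneuvers) are imputed at the
#' training mean (0 after scaling) and flagged.
#'
#' @param object an `osa_model`.
#' @param X raw acoustic feature matrix (subjects x 640).
#' @param meta metadata rows aligned with `X`.
#' @param threshold decision threshold (default from the model config).
#' @param mode fusion mode (default from the model config).
#' @param ... unused.
#' @return data.frame with `subject_id`, `p_final`, `label`,
#'   `n_relevant`, `imputed`; the per-subgroup probability matrix is
#'   attached as attribute `"prob_matrix"`.
#' @export
predict.osa_model <- function(object, X, meta, threshold = NULL,
                              mode = NULL, ...) {
  threshold <- threshold %||% object$config$threshold
  mode <- mode %||% object$config$mode
  Xz <- zscore_apply(object$scaler, X)
  imputed <- !stats::complete.cases(Xz)
  Xz[is.na(Xz)] <- 0
  membership <- subgroup_membership(meta)
  n <- nrow(Xz)
  pm <- matrix(NA_real_, n, length(subgroup_ids()),
               dimnames = list(meta$subject_id, subgroup_ids()))
  for (id in subgroup_ids()) {
    sc <- object$subclassifiers[[id]]
    if (is.null(sc)) next
    rows <- which(membership[, id])
    if (length(rows) == 0) next
    pm[rows, id] <- subclassifier_proba(sc, Xz[rows, , drop = FALSE],
                                        meta[rows, , drop = FALSE])
  }
  res <- lapply(seq_len(n), function(i) {
    fuse(pm[i, ], colnames(pm)[!is.na(pm[i, ])], threshold, mode)
  })
  out <- data.frame(subject_id = meta$subject_id,
                    p_final = vapply(res, `[[`, numeric(1), "p_final"),
                    label = vapply(res, `[[`, character(1), "label"),
                    n_relevant = rowSums(!is.na(pm)),
                    imputed = imputed,
                    stringsAsFactors = FALSE)
  attr(out, "prob_matrix") <- pm
  out
}

#' Cross-validated evaluation of the two-level framework
#'
#' Outer stratified k-fold over the binary (non-gap) population: trains
#' the full two-level model on each training split, predicts the held-out
#' fold, and reports per-fold and pooled metrics, the probability-vs-
#' majority voting comparison, a threshold sweep, leave-one-subgroup-out
#' fusion rows, and the intermediate-AHI group evaluated as an
#' independent test set on each fold's model.
#'
#' @param X raw acoustic feature matrix for all subjects (including gap).
#' @param meta metadata for all subjects (labels include
#'   `"excluded-gap"`).
#' @param config a [framework_config()].
#' @param seed integer seed.
#' @return an `osa_evaluation` list.
#' @export
evaluate_framework <- function(X, meta, config = framework_config(), seed = 1L) {
  is_gap <- meta$label == LABEL_GAP
  Xb <- X[!is_gap, , drop = FALSE]
  mb <- meta[!is_gap, , drop = FALSE]
  folds <- stratified_folds(mb$label, config$outer_k, derive_seed(seed, "outer"))

  per_fold <- list()
  pooled_p <- numeric(0); pooled_truth <- character(0)
  pooled_pm <- NULL
  pooled_major <- character(0)
  gap_frac <- numeric(0)
  models <- vector("list", length(folds))

  for (f in seq_along(folds)) {
    test <- folds[[f]]
    train <- setdiff(seq_len(nrow(Xb)), test)
    model <- train_osa_model(Xb[train, , drop = FALSE],
                             mb[train, , drop = FALSE], config,
                             seed = derive_seed(seed, "fold", f))
    models[[f]] <- model
    pred <- predict(model, Xb[test, , drop = FALSE], mb[test, , drop = FALSE])
    truth <- mb$label[test]
    m <- compute_metrics(confusion_counts(truth, pred$label))
    per_fold[[f]] <- data.frame(
      fold = f, accuracy = m$accuracy, sensitivity = m$sensitivity,
      specificity = m$specificity, balanced_accuracy = m$balanced_accuracy,
      auc = auc_score(pred$p_final, truth))
    pooled_p <- c(pooled_p, pred$p_final)
    pooled_truth <- c(pooled_truth, truth)
    pooled_pm <- rbind(pooled_pm, attr(pred, "prob_matrix"))
    pred_maj <- predict(model, Xb[test, , drop = FALSE],
                        mb[test, , drop = FALSE], mode = "majority")
    pooled_major <- c(pooled_major, pred_maj$label)
    if (any(is_gap)) {
      gp <- predict(model, X[is_gap, , drop = FALSE],
                    meta[is_gap, , drop = FALSE])
      gap_frac <- c(gap_frac, gap_fraction_osa(gp$p_final, config$threshold))
    }
  }

  per_fold <- do.call(rbind, per_fold)
  pooled_pred <- ifelse(pooled_p >= config$threshold, LABEL_OSA, LABEL_NON)
  pooled_cm <- confusion_counts(pooled_truth, pooled_pred)
  loso <- do.call(rbind, lapply(subgroup_ids(), function(id) {
    if (all(is.na(pooled_pm[, id]))) return(NULL)
    loso_fusion(pooled_pm, pooled_truth, id, config$threshold,
                on_empty = "drop")
  }))
  structure(list(
    per_fold = per_fold,
    summary = list(mean = colMeans(per_fold[-1], na.rm = TRUE),
                   sd = apply(per_fold[-1], 2, stats::sd, na.rm = TRUE)),
    pooled_confusion = pooled_cm,
    pooled_metrics = compute_metrics(pooled_cm),
    pooled_auc = auc_score(pooled_p, pooled_truth),
    majority_metrics = compute_metrics(confusion_counts(pooled_truth, pooled_major)),
    threshold_sweep = threshold_sweep(pooled_p, pooled_truth),
    loso = loso,
    gap = list(per_fold = gap_frac,
               mean = if (length(gap_frac)) mean(gap_frac) else NA_real_,
               sd = if (length(gap_frac) > 1) stats::sd(gap_frac) else NA_real_),
    predictions = data.frame(truth = pooled_truth, p_final = pooled_p,
                             pred = pooled_pred, stringsAsFactors = FALSE),
    prob_matrix = pooled_pm,
    folds = folds, config = config, seed = seed),
    class = "osa_evaluation")
}

#' Global non-stratified baseline
#'
#' A single bagged-trees ensemble on the whole training population (no
#' anthropometric stratification), evaluated on the same outer folds.
#' With `balanced = FALSE` (default) the trees are grown on ordinary
#' bootstrap samples — the standard bagged-trees comparator, which on
#' imbalanced data tends to collapse onto the majority class; with
#' `balanced = TRUE` the same balanced-subset scheme as the
#' sub-classifiers is used.
#'
#' @param X raw acoustic feature matrix (non-gap subjects).
#' @param meta metadata (non-gap subjects).
#' @param folds outer fold index lists (reuse the framework's folds).
#' @param config a [framework_config()].
#' @param balanced use balanced subsets instead of plain bootstrap.
#' @param hyper tree hyperparameters.
#' @param seed integer seed.
#' @return list with `per_fold` metrics and `pooled` metrics.
#' @export
global_baseline <- function(X, meta, folds, config = framework_config(),
                            balanced = FALSE,
                            hyper = list(maxdepth = 30L, minbucket = 3L),
                            seed = 1L) {
  per_fold <- list()
  pooled_p <- numeric(0); pooled_truth <- character(0)
  for (f in seq_along(folds)) {
    test <- folds[[f]]
    train <- setdiff(seq_len(nrow(X)), test)
    keep <- train[stats::complete.cases(X[train, , drop = FALSE])]
    scaler <- zscore_fit(X[keep, , drop = FALSE])
    Xz <- zscore_apply(scaler, X)
    Xz[is.na(Xz)] <- 0
    y <- meta$label
    st <- suppressWarnings(
      stability_select(Xz[keep, , drop = FALSE], y[keep], B = config$B,
                       k = config$k_features,
                       seed = derive_seed(seed, "baseline", f),
                       min_score = config$min_score))
    fset <- assemble_final(st$top_stable)
    tab <- table(factor(y[keep], levels = c(LABEL_NON, LABEL_OSA)))
    sz <- ensemble_size(max(tab), min(tab))
    df <- build_design(Xz[keep, , drop = FALSE], meta[keep, , drop = FALSE], fset)
    set.seed(derive_seed(seed, "baseline-bag", f))
    trees <- if (balanced) {
      subsets <- build_balanced_subsets(y[keep], sz$M,
                                        seed = derive_seed(seed, "baseline-sub", f))
      lapply(subsets, function(rows)
        fit_tree(df[rows, , drop = FALSE], y[keep][rows], hyper))
    } else {
      lapply(seq_len(sz$M), function(m) {
        rows <- sample(length(keep), length(keep), replace = TRUE)
        fit_tree(df[rows, , drop = FALSE], y[keep][rows], hyper)
      })
    }
    dft <- build_design(Xz[test, , drop = FALSE], meta[test, , drop = FALSE], fset)
    probs <- rowMeans(vapply(trees, function(tr)
      predict(tr, newdata = dft, type = "prob")[, LABEL_OSA],
      numeric(nrow(dft))))
    pred <- ifelse(probs >= config$threshold, LABEL_OSA, LABEL_NON)
    m <- compute_metrics(confusion_counts(y[test], pred))
    per_fold[[f]] <- data.frame(fold = f, accuracy = m$accuracy,
                                sensitivity = m$sensitivity,
                                specificity = m$specificity,
                                balanced_accuracy = m$balanced_accuracy)
    pooled_p <- c(pooled_p, probs)
    pooled_truth <- c(pooled_truth, y[test])
  }
  pooled_pred <- ifelse(pooled_p >= config$threshold, LABEL_OSA, LABEL_NON)
  list(per_fold = do.call(rbind, per_fold),
       pooled = compute_metrics(confusion_counts(pooled_truth, pooled_pred)))
}
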