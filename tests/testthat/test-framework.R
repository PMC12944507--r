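fast_fw <- function(...) {
  framework_config(B = 30, inner_repeats = 1,
                   hyper_grid = expand.grid(maxdepth = c(3L, 30L),
                                            minbucket = 3L), ...)
}

test_that("the two-level model trains, predicts and is deterministic", {
  fx <- feature_cohort(40, 20, 6, planted = c(25, 320), effect = 1.5, seed = 13)
  keep <- fx$meta$label != "excluded-gap"
  model <- train_osa_model(fx$X[keep, ], fx$meta[keep, ], fast_fw(), seed = 2)
  expect_s3_class(model, "osa_model")
  trained <- !vapply(model$subclassifiers, is.null, logical(1))
  expect_gt(sum(trained), 4)
  pred <- predict(model, fx$X, fx$meta)
  expect_equal(nrow(pred), nrow(fx$meta))
  expect_true(all(pred$p_final >= 0 & pred$p_final <= 1))
  expect_true(all(pred$n_relevant >= 1))
  ## fused probability lies inside the member range (convexity)
  pm <- attr(pred, "prob_matrix")
  rng <- t(apply(pm, 1, range, na.rm = TRUE))
  expect_true(all(pred$p_final >= rng[, 1] - 1e-12 &
                    pred$p_final <= rng[, 2] + 1e-12))
  ## determinism of the whole pipeline
  model2 <- train_osa_model(fx$X[keep, ], fx$meta[keep, ], fast_fw(), seed = 2)
  pred2 <- predict(model2, fx$X, fx$meta)
  expect_identical(pred$p_final, pred2$p_final)
  expect_identical(pred$label, pred2$label)
})

test_that("no training statistic leaks across the outer split", {
  fx <- feature_cohort(36, 18, 0, planted = 12, effect = 1.5, seed = 17)
  idx_train <- which(seq_len(nrow(fx$X)) %% 3 != 0)
  model <- train_osa_model(fx$X[idx_train, ], fx$meta[idx_train, ],
                           fast_fw(), seed = 4)
  ## the scaler is the training set's, not the population's
  expect_equal(model$scaler$center, colMeans(fx$X[idx_train, ]),
               tolerance = 1e-12)
  ## every bagged subset indexes training subjects only
  for (sc in Filter(Negate(is.null), model$subclassifiers)) {
    n_sub <- sum(subgroup_membership(fx$meta[idx_train, ])[, sc$subgroup_id])
    expect_true(all(unlist(sc$manifest$subsets) <= n_sub))
  }
})

test_that("subgroup-specific signal favors the matching sub-classifier", {
  ## opposite-signed acoustic markers in males and females (the kind of
  ## subgroup heterogeneity the stratified design targets): the male
  ## sub-classifier separates its stratum better than a pooled model
  ## trained identically on everyone (paired seeds)
  adv <- replicate(5, NA_real_)
  for (r in 1:5) {
    syn <- synthesis_config(class_counts = c("OSA" = 44, "non-OSA" = 22),
                            seed = 100 + r)
    coh <- generate_cohort(syn)
    set.seed(derive_seed(100 + r, "X"))
    X <- matrix(rnorm(nrow(coh) * 640), nrow(coh), 640)
    male_osa <- coh$sex == "male" & coh$label == "OSA"
    female_osa <- coh$sex == "female" & coh$label == "OSA"
    for (f in c(10, 20)) {
      X[male_osa, f] <- X[male_osa, f] + 2
      X[female_osa, f] <- X[female_osa, f] - 2
    }
    test_idx <- which(seq_len(nrow(coh)) %% 2 == 0)
    train_idx <- setdiff(seq_len(nrow(coh)), test_idx)
    males_tr <- train_idx[coh$sex[train_idx] == "male"]
    males_te <- test_idx[coh$sex[test_idx] == "male"]
    if (min(table(coh$label[males_tr])) < 3 ||
        length(unique(coh$label[males_te])) < 2) next
    fset <- assemble_final(c(10, 20, 101, 202, 303, 404, 505))
    hyper <- list(maxdepth = 5, minbucket = 3)
    sub <- train_subclassifier(X[males_tr, ], coh[males_tr, ], fset, hyper,
                               "male", seed = r)
    pooled <- train_subclassifier(X[train_idx, ], coh[train_idx, ], fset,
                                  hyper, "pooled", seed = r)
    bal <- function(model, rows) {
      p <- subclassifier_proba(model, X[rows, ], coh[rows, ])
      pred <- ifelse(p >= 0.5, "OSA", "non-OSA")
      compute_metrics(confusion_counts(coh$label[rows], pred))$balanced_accuracy
    }
    adv[r] <- bal(sub, males_te) - bal(pooled, males_te)
  }
  expect_gt(mean(adv, na.rm = TRUE), 0)
})

test_that("cross-validated evaluation produces a coherent report", {
  fx <- memo("eval_fixture", {
    fx <- feature_cohort(44, 22, 6, planted = c(60, 330, 600),
                         effect = 1.5, seed = 19)
    ev <- evaluate_framework(fx$X, fx$meta, fast_fw(outer_k = 3L), seed = 23)
    list(fx = fx, ev = ev)
  })
  ev <- fx$ev
  expect_equal(nrow(ev$per_fold), 3)
  ## pooled confusion equals the population split
  cm <- ev$pooled_confusion
  expect_equal(cm$tp + cm$fn, 44)
  expect_equal(cm$tn + cm$fp, 22)
  ## balanced accuracy identity holds per fold
  expect_equal(ev$per_fold$balanced_accuracy,
               (ev$per_fold$sensitivity + ev$per_fold$specificity) / 2)
  ## planted signal is learnable
  expect_gt(ev$pooled_metrics$balanced_accuracy, 60)
  expect_gt(ev$pooled_auc, 0.6)
  ## threshold sweep contains the operating point
  at05 <- ev$threshold_sweep[abs(ev$threshold_sweep$threshold - 0.5) < 1e-9, ]
  expect_equal(at05$accuracy, ev$pooled_metrics$accuracy)
  ## LOSO rows exist for trained subgroups and stay in range
  expect_true(all(ev$loso$balanced_accuracy >= 0 &
                    ev$loso$balanced_accuracy <= 100))
  ## gap group evaluated per fold
  expect_length(ev$gap$per_fold, 3)
  expect_true(all(ev$gap$per_fold >= 0 & ev$gap$per_fold <= 1))
})
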