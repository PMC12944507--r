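test_that("subgroup assignment follows the stratification thresholds", {
  s1 <- list(sex = "male", age = 55, bmi = 36, mps = 3, smoking = "current")
  k1 <- assign_subgroups(s1)
  expect_setequal(k1, c("male", "high_age", "high_bmi", "high_mps"))
  expect_length(k1, 4)  # current smokers miss the ninth stratum
  ## boundary values fall to the low side; non-smokers gain the stratum
  s2 <- list(sex = "female", age = 50, bmi = 35, mps = 2, smoking = "never")
  k2 <- assign_subgroups(s2)
  expect_setequal(k2, c("female", "low_age", "low_bmi", "low_mps",
                        "non_current_smokers"))
  expect_error(assign_subgroups(list(sex = "male", age = NA, bmi = 30,
                                     mps = 1, smoking = "never")),
               "missing")
})

test_that("every subject matches exactly one of each complementary pair", {
  coh <- generate_cohort(small_syn_config())
  m <- subgroup_membership(coh)
  pairs <- list(c("male", "female"), c("high_age", "low_age"),
                c("high_bmi", "low_bmi"), c("high_mps", "low_mps"))
  for (p in pairs) expect_true(all(rowSums(m[, p]) == 1))
  expect_equal(unname(m[, "non_current_smokers"]),
               coh$smoking %in% c("never", "former"))
})

test_that("ensemble sizing follows the ceiling of the class ratio", {
  s <- ensemble_size(99, 19)
  expect_equal(round_half_up(s$ratio, 2), 5.21)
  expect_equal(s$Nmin, 6L)
  expect_equal(s$M, 18L)
  s2 <- ensemble_size(121, 40)
  expect_equal(round_half_up(s2$ratio, 2), 3.03)
  expect_equal(s2$Nmin, 4L)
  expect_equal(s2$M, 12L)
  expect_equal(ensemble_size(10, 10)$Nmin, 1L)
  expect_equal(ensemble_size(10, 10)$M, 3L)
  expect_error(ensemble_size(10, 0), "empty")
})

test_that("balanced subsets cover every majority subject per block", {
  y <- rep(c("OSA", "non-OSA"), c(99, 19))
  subsets <- build_balanced_subsets(y, 18, seed = 4)
  expect_length(subsets, 18)
  expect_true(all(lengths(subsets) == 38))
  minority <- which(y == "non-OSA")
  majority <- which(y == "OSA")
  for (s in subsets) expect_true(all(minority %in% s))
  ## each of the 3 blocks of Nmin = 6 subsets partitions the majority
  cnt <- table(factor(unlist(subsets), levels = majority))
  expect_true(all(cnt >= 3))
  expect_setequal(unique(unlist(lapply(subsets, intersect, majority))),
                  majority)
  ## balanced classes: each of the 3 subsets is everybody once
  yb <- rep(c("OSA", "non-OSA"), each = 10)
  sb <- build_balanced_subsets(yb, 3, seed = 1)
  for (s in sb) expect_equal(sort(s), 1:20)
  ## determinism
  expect_identical(build_balanced_subsets(y, 18, seed = 4), subsets)
})

test_that("sub-classifiers train M trees deterministically", {
  fx <- feature_cohort(30, 12, 0, planted = c(3, 44), effect = 2, seed = 6)
  fset <- assemble_final(c(3, 44, 100, 200, 300, 400, 500))
  hyper <- list(maxdepth = 5, minbucket = 3)
  sc <- train_subclassifier(fx$X, fx$meta, fset, hyper, "male", seed = 2)
  expect_s3_class(sc, "sub_classifier")
  expect_equal(sc$M, 3L * sc$Nmin)
  expect_length(sc$trees, sc$M)
  ## coverage invariant recorded in the manifest
  majority <- which(fx$meta$label == "OSA")
  expect_setequal(intersect(unlist(sc$manifest$subsets), majority), majority)
  ## same seed, same ensemble
  sc2 <- train_subclassifier(fx$X, fx$meta, fset, hyper, "male", seed = 2)
  p1 <- subclassifier_proba(sc, fx$X, fx$meta)
  p2 <- subclassifier_proba(sc2, fx$X, fx$meta)
  expect_identical(p1, p2)
  ## a single-class subgroup is untrainable
  one <- fx$meta$label == "OSA"
  expect_null(train_subclassifier(fx$X[one, ], fx$meta[one, ], fset, hyper))
})

test_that("ensemble probability equals the brute-force tree average", {
  fx <- feature_cohort(30, 12, 0, planted = 7, effect = 1.5, seed = 8)
  fset <- assemble_final(c(7, 50, 150, 250, 350, 450, 550))
  sc <- train_subclassifier(fx$X, fx$meta, fset,
                            list(maxdepth = 30, minbucket = 1), "g", seed = 3)
  df <- osascreen:::build_design(fx$X, fx$meta, fset)
  brute <- rowMeans(vapply(sc$trees, function(tr)
    predict(tr, newdata = df, type = "prob")[, "OSA"], numeric(nrow(df))))
  expect_equal(subclassifier_proba(sc, fx$X, fx$meta), brute,
               tolerance = 1e-12)
  expect_true(all(brute >= 0 & brute <= 1))
})

test_that("fusion averages the relevant members and breaks ties to OSA", {
  probs <- c(male = 0.6, high_age = 0.6, high_bmi = 0.2, high_mps = 0.2,
             non_current_smokers = 0.2)
  f <- fuse(probs, names(probs))
  expect_equal(f$p_final, 0.36)
  expect_equal(f$label, "non-OSA")
  fm <- fuse(probs, names(probs), mode = "majority")
  expect_equal(fm$label, "non-OSA")   # 2 of 5 votes
  ## exact threshold goes to OSA
  expect_equal(fuse(c(a = 0.5), "a")$label, "OSA")
  ## all members agreeing return their common value
  expect_equal(fuse(c(a = 0.42, b = 0.42, c = 0.42), c("a", "b", "c"))$p_final,
               0.42)
  ## tie at 2-2 in majority mode resolves to OSA
  t4 <- fuse(c(a = 0.9, b = 0.9, c = 0.1, d = 0.1), letters[1:4],
             mode = "majority")
  expect_equal(t4$label, "OSA")
  expect_error(fuse(c(a = NA_real_), "a"), "empty Kx")
})

test_that("fusion is a convex, monotone combination", {
  set.seed(41)
  for (i in 1:30) {
    k <- sample(4:5, 1)
    p <- stats::runif(k)
    names(p) <- paste0("s", seq_len(k))
    f <- fuse(p, names(p))
    expect_gte(f$p_final, min(p))
    expect_lte(f$p_final, max(p))
    ## raising any single member never flips OSA -> non-OSA
    if (f$label == "OSA") {
      j <- sample(k, 1)
      p2 <- p
      p2[j] <- min(1, p2[j] + stats::runif(1))
      expect_equal(fuse(p2, names(p2))$label, "OSA")
    }
  }
})
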