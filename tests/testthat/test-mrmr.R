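test_that("mutual information matches analytic values", {
  y <- rep(c("a", "b"), 50)
  expect_equal(mutual_information(factor(y), factor(y)), log(2))
  ## the 2x2 diagonal table {{50,0},{0,50}} carries ln 2 nats
  x <- rep(c(0, 1), each = 50)
  cls <- rep(c("p", "q"), each = 50)
  expect_equal(mutual_information(x, cls), log(2))
  ## independence decays with n
  set.seed(31)
  mi_small <- mutual_information(rnorm(50), sample(c("a", "b"), 50, TRUE))
  mi_large <- mutual_information(rnorm(5000), sample(c("a", "b"), 5000, TRUE))
  expect_lt(mi_large, mi_small)
  expect_lt(mi_large, 0.005)
})

test_that("greedy mRMR picks signal first and shuns duplicates", {
  set.seed(32)
  n <- 200
  y <- rep(c("OSA", "non-OSA"), each = n / 2)
  X <- matrix(rnorm(n * 10), n, 10)
  X[, 4] <- ifelse(y == "OSA", 1.5, 0) + rnorm(n)  # strongest predictor
  X[, 7] <- X[, 4]                                 # exact duplicate
  X[, 9] <- ifelse(y == "OSA", 1.2, 0) + rnorm(n)  # informative, distinct
  res <- mrmr_select(X, y, k = 3)
  expect_equal(res$selected[1], 4L)   # smallest index among tied duplicates
  expect_false(res$selected[2] == 7L) # duplicate fully redundant
  expect_true(9L %in% res$selected)
  ## pure noise with a score floor returns a short list
  Xn <- matrix(rnorm(4000 * 5), 4000, 5)
  resn <- mrmr_select(Xn, rep(c("OSA", "non-OSA"), 2000), k = 5)
  expect_lt(length(resn$selected), 5)
  expect_equal(mrmr_select(X[, 0, drop = FALSE], y)$selected, integer(0))
})

test_that("greedy trace equals the brute-force oracle step for step", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- 80
    p <- sample(4:8, 1)
    y <- rep(c("OSA", "non-OSA"), length.out = n)
    X <- matrix(rnorm(n * p), n, p)
    X[, 1] <- X[, 1] + ifelse(y == "OSA", 0.8, 0)
    X[, 2] <- X[, 1] + 0.3 * rnorm(n)
    got <- mrmr_select(X, y, k = 3, min_score = 0)
    want <- oracle_mrmr(X, y, k = 3, min_score = 0)
    expect_equal(got$selected, want$selected)
    expect_equal(got$scores, want$scores, tolerance = 1e-10)
    ## the first pick is the exhaustive argmax-relevance feature
    rel <- vapply(seq_len(p), function(j) mutual_information(X[, j], y),
                  numeric(1))
    expect_equal(got$selected[1], which.max(rel))
  }
})

test_that("stability selection is deterministic and counts are bounded", {
  fx <- feature_cohort(40, 20, 0, planted = 5, effect = 2, seed = 3)
  keep <- fx$meta$label != "excluded-gap"
  st1 <- stability_select(fx$X[keep, ], fx$meta$label[keep], B = 50, seed = 9)
  st2 <- stability_select(fx$X[keep, ], fx$meta$label[keep], B = 50, seed = 9)
  expect_identical(st1, st2)
  expect_lte(sum(st1$selection_count), 50 * 7)
  expect_true(all(st1$selection_count <= 50))
  expect_true(5 %in% st1$top_stable)
  ## swapped classes warn
  y_sw <- rep(c("OSA", "non-OSA"), c(10, 30))
  expect_warning(
    stability_select(matrix(rnorm(40 * 8), 40, 8), y_sw, B = 5, seed = 1),
    "swapped")
})

test_that("null data produces no reproducibly stable feature", {
  ## Because every balanced subset contains the full minority class,
  ## selection frequencies are correlated across subsets and a chance
  ## association can recur within one labeling. Exchangeability instead
  ## shows up across independent label permutations: the top-ranked
  ## feature changes, while a genuinely informative feature stays on top.
  set.seed(35)
  n <- 120; p <- 80; B <- 60
  X <- matrix(rnorm(n * p), n, p)
  top_null <- vapply(1:5, function(r) {
    y <- sample(rep(c("OSA", "non-OSA"), c(80, 40)))
    st <- stability_select(X, y, B = B, seed = r)
    st$top_stable[1]
  }, integer(1))
  expect_lt(max(table(top_null)), 4)   # no feature tops >= 4 of 5 permutations
  ## contrast: a planted signal tops every permutation-free refit
  Xs <- X
  y0 <- rep(c("OSA", "non-OSA"), c(80, 40))
  Xs[y0 == "OSA", 13] <- Xs[y0 == "OSA", 13] + 1.5
  top_sig <- vapply(1:5, function(r)
    stability_select(Xs, y0, B = B, seed = r)$top_stable[1], integer(1))
  expect_true(all(top_sig == 13L))
})

test_that("consensus ranking counts recurrence with index tie-breaks", {
  sets <- list(c(1, 2, 3), c(1, 2, 3), c(1, 2, 3), c(1, 2, 3))
  expect_equal(consensus_rank(sets, 3), c(1L, 2L, 3L))
  sets2 <- list(c(5, 9), c(5, 9), c(5, 2), c(5, 2, 9))
  r <- consensus_rank(sets2, 2)
  expect_equal(r[1], 5L)
  expect_equal(r[2], 9L)   # 9 appears 3x vs 2 appearing 2x
  expect_equal(consensus_rank(list(c(4L, 8L)), 7), c(4L, 8L))
})

test_that("final assembly appends the three anthropometric features", {
  subject <- list(neck_circumference = 41.5, snoring = TRUE,
                  receding_mandible = 1)
  fs <- assemble_final(c(9, 113, 362, 410, 473, 522, 616), subject)
  expect_equal(fs$total, 10)
  expect_equal(fs$anthro,
               c("neck_circumference", "snoring", "receding_mandible"))
  expect_error(
    assemble_final(1:7, list(neck_circumference = NA, snoring = TRUE,
                             receding_mandible = 0)),
    "missing anthropometric")
})
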