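## ---------------------------------------------------------------------------
## Level-1 classifiers: per-subgroup ensembles of bagged decision trees
## trained on balanced subsets, and level-2 fusion by dynamic selection
## (averaging the sub-classifiers relevant to a subject's profile).
## ---------------------------------------------------------------------------

#' Ensemble sizing from the class ratio
#'
#' `Nmin = ceiling(n_majority / n_minority)` is the minimum number of
#' balanced subsets needed so every majority-class subject can appear;
#' the tree count is `M = 3 * Nmin`.
#'
#' @param n_majority majority-class (typically OSA) training count.
#' @param n_minority minority-class (typically non-OSA) training count.
#' @return list with `ratio`, `Nmin`, `M`.
#' @export
ensemble_size <- function(n_majority, n_minority) {
  if (n_minority < 1) stopf("minority class is empty")
  ratio <- n_majority / n_minority
  Nmin <- as.integer(ceiling(ratio))
  list(ratio = ratio, Nmin = Nmin, M = 3L * Nmin)
}

#' Build balanced training subsets
#'
#' Each subset contains every minority-class index plus `n_minority`
#' majority-class indices. Within each consecutive block of `Nmin`
#' subsets the majority indices form a shuffled partition (the last
#' subset of a block is padded by resampling indices already used in the
#' block), so the union over any block — and hence over all `M` subsets —
#' covers every majority subject.
#'
#' @param labels binary labels (the minority class is inferred).
#' @param M number of subsets (a multiple of `Nmin` covers all blocks).
#' @param seed integer seed.
#' @return list of `M` integer index vectors.
#' @export
build_balanced_subsets <- function(labels, M, seed = 1L) {
  y <- as.integer(factor(labels)) - 1L
  idx0 <- which(y == 0L); idx1 <- which(y == 1L)
  if (length(idx0) <= length(idx1)) {
    minority <- idx0; majority <- idx1
  } else {
    minority <- idx1; majority <- idx0
  }
  n_min <- length(minority); n_maj <- length(majority)
  if (n_min < 1) stopf("minority class is empty")
  Nmin <- as.integer(ceiling(n_maj / n_min))
  if (M < Nmin) stopf("M = %d below the coverage minimum Nmin = %d", M, Nmin)
  set.seed(derive_seed(seed, "subsets"))
  subsets <- vector("list", M)
  s <- 0L
  while (s < M) {
    perm <- sample(majority)
    for (g in seq_len(Nmin)) {
      if (s >= M) break
      s <- s + 1L
      lo <- (g - 1L) * n_min + 1L
      hi <- min(g * n_min, n_maj)
      grp <- perm[lo:hi]
      if (length(grp) < n_min) {
        pad <- sample(perm[seq_len(lo - 1L)], n_min - length(grp))
        grp <- c(grp, pad)
      }
      subsets[[s]] <- sort(c(minority, grp))
    }
  }
  subsets
}

## Design data.frame for the trees: selected acoustic columns (named
## f<index>) + the three anthropometric features encoded numerically.
build_design <- function(X, meta, feature_set) {
  df <- as.data.frame(X[, feature_set$acoustic, drop = FALSE])
  names(df) <- paste0("f", feature_set$acoustic)
  df$neck_circumference <- meta$neck_circumference
  df$snoring <- as.numeric(meta$snoring)
  df$receding_mandible <- as.numeric(meta$receding_mandible)
  df
}

fit_tree <- function(df, y, hyper) {
  dat <- df
  dat$.y <- factor(y, levels = c(LABEL_NON, LABEL_OSA))
  rpart::rpart(.y ~ ., data = dat, method = "class",
               control = rpart::rpart.control(
                 maxdepth = hyper$maxdepth,
                 minbucket = hyper$minbucket,
                 minsplit = max(2L, 2L * hyper$minbucket),
                 cp = 0, xval = 0))
}

#' Train one anthropometric sub-classifier
#'
#' Fits `M = 3 * Nmin` probability-output decision trees, one per
#' balanced subset, on the subgroup's training subjects restricted to the
#' final 10 features.
#'
#' @param X z-scored acoustic feature matrix (training subjects x 640).
#' @param meta training metadata rows (anthropometrics + labels).
#' @param feature_set an [assemble_final()] result.
#' @param hyper list with `maxdepth`, `minbucket`.
#' @param subgroup_id subgroup identifier (for the manifest).
#' @param seed integer seed.
#' @return a `sub_classifier` object, or `NULL` (untrainable) if only one
#'   class is present.
#' @export
train_subclassifier <- function(X, meta, feature_set, hyper,
                                subgroup_id = "subgroup", seed = 1L) {
  y <- meta$label
  tab <- table(factor(y, levels = c(LABEL_NON, LABEL_OSA)))
  if (any(tab == 0)) return(NULL)
  sz <- ensemble_size(max(tab), min(tab))
  subsets <- build_balanced_subsets(y, sz$M, seed = derive_seed(seed, subgroup_id))
  df <- build_design(X, meta, feature_set)
  trees <- lapply(seq_along(subsets), function(m) {
    rows <- subsets[[m]]
    fit_tree(df[rows, , drop = FALSE], y[rows], hyper)
  })
  structure(list(subgroup_id = subgroup_id, features = feature_set,
                 trees = trees, M = sz$M, Nmin = sz$Nmin, ratio = sz$ratio,
                 hyper = hyper,
                 manifest = list(subsets = subsets, seed = seed,
                                 n_majority = max(tab), n_minority = min(tab))),
            class = "sub_classifier")
}

#' Average tree probability of one sub-classifier
#'
#' Arithmetic mean over the ensemble's trees of the OSA leaf probability.
#'
#' @param model a `sub_classifier`.
#' @param X z-scored acoustic matrix for the queried subjects.
#' @param meta metadata rows aligned with `X`.
#' @return numeric vector of OSA probabilities in `[0, 1]`.
#' @export
subclassifier_proba <- function(model, X, meta) {
  df <- build_design(X, meta, model$features)
  probs <- vapply(model$trees, function(tr) {
    p <- predict(tr, newdata = df, type = "prob")
    p[, LABEL_OSA]
  }, numeric(nrow(df)))
  if (nrow(df) == 1L) probs <- matrix(probs, nrow = 1)
  rowMeans(probs)
}

#' Fuse sub-classifier probabilities into the final prediction
#'
#' Probability mode averages the probabilities of the relevant
#' sub-classifiers (the subject's set Kx); majority mode lets each
#' relevant member vote at 0.5 with ties going to OSA (screening
#' prioritizes sensitivity). The final label is OSA when the fused
#' probability is at or above `threshold`.
#'
#' @param probs named numeric vector of per-subgroup OSA probabilities.
#' @param Kx character vector of relevant subgroup ids (members missing
#'   from `probs` — e.g. untrainable subgroups — are ignored).
#' @param threshold decision threshold (default 0.5).
#' @param mode `"probability"` (default) or `"majority"`.
#' @return list with `p_final`, `label`, `Kx_used`.
#' @export
fuse <- function(probs, Kx, threshold = 0.5,
                 mode = c("probability", "majority")) {
  mode <- match.arg(mode)
  use <- intersect(Kx, names(probs)[!is.na(probs)])
  if (length(use) == 0) stopf("no relevant sub-classifier available (empty Kx)")
  pk <- probs[use]
  if (mode == "probability") {
    p_final <- mean(pk)
    label <- if (p_final >= threshold) LABEL_OSA else LABEL_NON
  } else {
    votes <- sum(pk >= 0.5)
    p_final <- votes / length(pk)
    label <- if (votes >= length(pk) / 2) LABEL_OSA else LABEL_NON
  }
  list(p_final = unname(p_final), label = label, Kx_used = use)
}
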