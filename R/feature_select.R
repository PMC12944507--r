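## ---------------------------------------------------------------------------
## Feature selection: mutual information by discretization, greedy mRMR
## (difference form), balanced-subset stability selection, cross-fold
## consensus ranking and final 10-feature assembly.
## ---------------------------------------------------------------------------

#' Discretize a numeric vector into three bins at mean +/- 0.5 sd
#'
#' The classic mRMR discretization scheme.
#'
#' @param x numeric vector.
#' @return integer codes in `{1, 2, 3}`.
#' @export
discretize3 <- function(x) {
  m <- mean(x)
  half <- 0.5 * stats::sd(x)
  if (!is.finite(half)) half <- 0
  ifelse(x < m - half, 1L, ifelse(x > m + half, 3L, 2L))
}

#' Plug-in mutual information (nats)
#'
#' Discretizes continuous inputs (3 bins at mean +/- 0.5 sd for
#' `bins = 3`, quantile bins otherwise; factors/characters/logicals and
#' integer-coded variables with few levels are used as-is) and computes
#' the plug-in MI of the joint distribution.
#'
#' @param x numeric vector or discrete variable.
#' @param y discrete variable (e.g. class labels).
#' @param bins number of bins for continuous `x`.
#' @return mutual information in nats (>= 0).
#' @export
mutual_information <- function(x, y, bins = 3L) {
  stopifnot(length(x) == length(y), length(x) >= 4)
  disc <- function(v) {
    if (is.factor(v) || is.character(v) || is.logical(v)) return(as.integer(factor(v)))
    u <- unique(v)
    if (length(u) <= bins) return(match(v, sort(u)))
    if (bins == 3L) return(discretize3(v))
    br <- unique(stats::quantile(v, probs = seq(0, 1, length.out = bins + 1)))
    as.integer(cut(v, br, include.lowest = TRUE))
  }
  a <- disc(x); b <- disc(y)
  tab <- table(a, b)
  n <- sum(tab)
  pj <- tab / n
  pa <- rowSums(pj); pb <- colSums(pj)
  nz <- pj > 0
  mi <- sum(pj[nz] * log(pj[nz] / outer(pa, pb)[nz]))
  max(mi, 0)
}

#' Greedy mRMR feature selection (difference form)
#'
#' Selects up to `k` features by forward greedy search: the first feature
#' maximizes relevance `I(f; y)`; subsequent steps maximize
#' `I(f; y) - |S|^(-e) * sum_{s in S} I(f; s)` with `e = 1` (the greedy
#' difference criterion; `e = 2` gives the set-objective normalization).
#' Selection stops early when the best step score drops below
#' `min_score`. Ties resolve to the smallest feature index.
#'
#' @param X numeric matrix (samples x features).
#' @param y binary class labels (factor, character or 0/1).
#' @param k maximum number of features (default 7).
#' @param min_score minimum step objective (default 0.01).
#' @param redundancy_exponent 1 (default) or 2.
#' @return list with `selected` (ordered indices) and `scores`.
#' @export
mrmr_select <- function(X, y, k = 7L, min_score = 0.01,
                        redundancy_exponent = 1) {
  X <- as.matrix(X)
  if (ncol(X) == 0) return(list(selected = integer(0), scores = numeric(0)))
  y01 <- as.integer(factor(y)) - 1L
  if (length(unique(y01)) < 2 && nrow(X) > 0)
    return(list(selected = integer(0), scores = numeric(0)))
  res <- mrmr_greedy_cpp(X, seq_len(nrow(X)), y01, as.integer(k),
                         min_score, redundancy_exponent)
  list(selected = as.integer(res$selected), scores = as.numeric(res$scores))
}

#' Balanced-subset stability selection
#'
#' Repeats greedy mRMR over `B` balanced subsets, each combining all
#' minority-class samples with an equal-size draw (without replacement)
#' of majority-class samples, and counts how often each feature is
#' selected. The subsets are independent across iterations.
#'
#' @param X numeric matrix (samples x features).
#' @param y binary class labels.
#' @param B number of balanced subsets (study value 1000).
#' @param k features retained per subset.
#' @param seed integer seed (deterministic profile).
#' @param min_score greedy stop threshold.
#' @return list with `selection_count` (length `ncol(X)`), `B`,
#'   `top_stable` (up to `k` indices by descending count, ties to the
#'   smaller index).
#' @export
stability_select <- function(X, y, B = 1000L, k = 7L, seed = 1L,
                             min_score = 0.01) {
  X <- as.matrix(X)
  y01 <- as.integer(factor(y)) - 1L
  stopifnot(length(unique(y01)) == 2)
  lev <- levels(factor(y))
  pos <- if (LABEL_OSA %in% lev) LABEL_OSA else lev[2]
  idx_pos <- which(y == pos); idx_neg <- which(y != pos)
  ## the nominal majority is the positive (typically OSA) class
  if (length(idx_pos) >= length(idx_neg)) {
    minority <- idx_neg; majority <- idx_pos
  } else {
    warning("majority class smaller than minority; classes swapped")
    minority <- idx_pos; majority <- idx_neg
  }
  if (length(minority) < 2) stopf("minority class needs >= 2 samples")
  set.seed(derive_seed(seed, "stability"))
  counts <- integer(ncol(X))
  for (b in seq_len(B)) {
    rows <- c(minority, sample(majority, length(minority)))
    res <- mrmr_greedy_cpp(X, rows, y01[rows], as.integer(k), min_score, 1)
    sel <- as.integer(res$selected)
    counts[sel] <- counts[sel] + 1L
  }
  ord <- order(-counts, seq_along(counts))
  top <- ord[seq_len(min(k, sum(counts > 0)))]
  list(selection_count = counts, B = as.integer(B),
       top_stable = as.integer(top))
}

#' Consensus ranking of candidate feature sets
#'
#' Pools the stable candidate sets found across inner cross-validation
#' folds and repeats, and returns the `k` features with the highest
#' recurrence (ties to the smaller index). If fewer than `k` distinct
#' candidates exist, all are returned.
#'
#' @param candidate_sets list of integer vectors.
#' @param k number of features to return (default 7).
#' @return integer vector of up to `k` feature indices.
#' @export
consensus_rank <- function(candidate_sets, k = 7L) {
  stopifnot(length(candidate_sets) >= 1)
  all_idx <- unlist(candidate_sets)
  if (length(all_idx) == 0) return(integer(0))
  tab <- table(all_idx)
  idx <- as.integer(names(tab))
  ord <- order(-as.integer(tab), idx)
  out <- idx[ord]
  out[seq_len(min(k, length(out)))]
}

#' Assemble the final 10-feature set
#'
#' Seven stable acoustic features plus the three fixed anthropometric
#' features (neck circumference, snoring, receding mandible), acoustic
#' first.
#'
#' @param acoustic integer vector of acoustic feature indices.
#' @param subject a cohort row supplying the anthropometric values.
#' @return list with `acoustic`, `anthro` (names), `total`.
#' @export
assemble_final <- function(acoustic,
                           subject = NULL) {
  anthro <- c("neck_circumference", "snoring", "receding_mandible")
  if (!is.null(subject)) {
    vals <- unlist(subject[anthro])
    if (length(vals) < 3 || anyNA(vals))
      stopf("missing anthropometric value(s) at assembly")
  }
  list(acoustic = as.integer(acoustic), anthro = anthro,
       total = length(acoustic) + length(anthro))
}
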