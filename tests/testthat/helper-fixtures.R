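## Shared small-scale fixtures. Audio fixtures run at 8 kHz so module
## tests stay fast; band edges scale with the rate. Expensive objects are
## computed once per test run and memoized here.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixtures)) {
    assign(key, force(expr), envir = .fixtures)
  }
  get(key, envir = .fixtures)
}

small_syn_config <- function(...) {
  synthesis_config(
    class_counts = c("OSA" = 10, "non-OSA" = 6, "excluded-gap" = 2),
    fs = 8000, cycles_per_maneuver = 2, silent_duration = 1.5,
    phase_duration_range = c(0.8, 1.2), seed = 42, ...)
}

small_pre_config <- function(...) {
  preprocess_config(antialias_band_hz = c(75, 900),
                    clean_band_hz = c(75, 800), ...)
}

## Feature-level cohort: metadata from the generator, acoustic features
## white noise with optional planted class effects (no audio involved).
feature_cohort <- function(n_osa = 60, n_non = 30, n_gap = 0,
                           planted = integer(0), effect = 1, seed = 1) {
  syn <- synthesis_config(
    class_counts = c("OSA" = n_osa, "non-OSA" = n_non, "excluded-gap" = n_gap),
    seed = seed)
  cohort <- generate_cohort(syn)
  set.seed(derive_seed(seed, "features"))
  X <- matrix(rnorm(nrow(cohort) * 640), nrow(cohort), 640)
  w <- ifelse(cohort$label == "OSA", 1,
              ifelse(cohort$label == "excluded-gap", 0.5, 0))
  for (f in planted) X[, f] <- X[, f] + effect * w
  list(X = X, meta = cohort)
}

## Pure-R brute-force greedy mRMR used as an independent oracle for the
## C++ implementation: same discretization, same difference objective.
oracle_mrmr <- function(X, y, k, min_score = 0.01) {
  disc <- apply(X, 2, discretize3)
  yd <- as.integer(factor(y))
  mi <- function(a, b) mutual_information(factor(a), factor(b))
  rel <- apply(disc, 2, mi, b = yd)
  selected <- integer(0)
  scores <- numeric(0)
  while (length(selected) < k) {
    cand <- setdiff(seq_len(ncol(X)), selected)
    obj <- vapply(cand, function(j) {
      if (length(selected) == 0) return(rel[j])
      rel[j] - mean(vapply(selected, function(s) mi(disc[, j], disc[, s]),
                           numeric(1)))
    }, numeric(1))
    best <- cand[which.max(obj)]
    if (max(obj) < min_score) break
    selected <- c(selected, best)
    scores <- c(scores, max(obj))
  }
  list(selected = selected, scores = scores)
}

## Segment intersection-over-union of two [start, end] spans.
span_iou <- function(a, b) {
  inter <- max(0, min(a[2], b[2]) - max(a[1], b[1]) + 1)
  inter / (max(a[2], b[2]) - min(a[1], b[1]) + 1)
}
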