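#' Derive a reproducible child seed from a global seed and context tokens
#'
#' A single user-supplied seed fans out to per-stage, per-subgroup and
#' per-tree seeds through a deterministic string hash, so that independent
#' pipeline stages never consume overlapping random streams and every
#' manifest records an exact reseeding point.
#'
#' @param seed integer global seed.
#' @param ... context tokens (strings or integers), e.g. `"stability"`,
#'   a fold number, a subgroup id.
#' @return an integer in `[1, 2^31 - 2]` suitable for `set.seed()`.
#' @export
derive_seed <- function(seed, ...) {
  tokens <- paste(c(seed, ...), collapse = "/")
  h <- as.double(seed %% 2147483647L)
  for (ch in utf8ToInt(tokens)) {
    h <- (h * 131 + ch) %% 2147483647
  }
  as.integer(h) + 1L
}

#' Round half up
#'
#' Rounds halves away from zero (the convention of clinical report
#' tables), unlike `round()`, which rounds half to even.
#'
#' @param x numeric vector.
#' @param digits decimal places (default 1).
#' @return rounded vector.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

## Stable hash of an R object (lists of numbers/strings) for manifests.
## Not cryptographic; just change-detection.
object_hash <- function(x) {
  s <- paste(deparse(x, control = c("keepNA", "niceNames")), collapse = "\n")
  h1 <- 216613626
  h2 <- 40009
  for (ch in utf8ToInt(s)) {
    h1 <- (h1 * 131 + ch) %% 2147483647
    h2 <- (h2 * 31 + ch) %% 2147483629
  }
  sprintf("%08x%08x", as.integer(h1), as.integer(h2))
}

## Centered moving average with window w (odd or even); edges use the
## available samples only, so output length equals input length.
moving_average <- function(x, w) {
  n <- length(x)
  if (w <= 1L || n == 0L) return(x)
  cs <- cumsum(c(0, x))
  half_l <- floor((w - 1) / 2)
  half_r <- w - 1 - half_l
  i <- seq_len(n)
  lo <- pmax(i - half_l, 1L)
  hi <- pmin(i + half_r, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
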