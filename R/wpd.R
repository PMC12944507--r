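## ---------------------------------------------------------------------------
## Wavelet packet decomposition (sym8, 5 levels) with frequency-ordered
## terminal nodes. The transform is implemented as the standard orthogonal
## two-channel filter bank with periodized boundaries, so the 32 terminal
## sub-bands form an exact orthogonal partition of the input energy.
## ---------------------------------------------------------------------------

## Symlet-8 scaling (decomposition low-pass) filter; standard published
## coefficients of the orthonormal sym8 wavelet (sum = sqrt(2)).
SYM8_DEC_LO <- c(
  -0.0033824159510061256, -0.0005421323317911481, 0.03169508781149298,
  0.007607487324917605, -0.1432942383508097, -0.061273359067658524,
  0.4813596512583722, 0.7771857517005235, 0.3644418948353314,
  -0.05194583810770904, -0.027219029917056003, 0.049137179673607506,
  0.003808752013890615, -0.01495225833704823, -0.0003029205147213668,
  0.0018899503327594609)

#' Wavelet-packet feature configuration
#'
#' @param wavelet mother wavelet (only `"sym8"` is provided).
#' @param levels decomposition depth (default 5 -> 32 terminal bands).
#' @param n_bands_kept leading frequency-ordered bands used for features.
#' @param tsallis_q Tsallis entropy order.
#' @param renyi_alpha Renyi entropy order.
#' @param spectrum_estimator `"coefficients"` (periodogram of the band's
#'   coefficient sequence; default) or `"reconstruction"` (periodogram of
#'   the band-limited reconstruction at the original rate).
#' @return a `wpd_config` list.
#' @export
wpd_config <- function(wavelet = "sym8", levels = 5L, n_bands_kept = 10L,
                       tsallis_q = 2, renyi_alpha = 2,
                       spectrum_estimator = c("coefficients", "reconstruction")) {
  stopifnot(identical(wavelet, "sym8"), levels >= 1,
            n_bands_kept <= 2^levels)
  structure(list(wavelet = wavelet, levels = as.integer(levels),
                 n_bands_kept = as.integer(n_bands_kept),
                 tsallis_q = tsallis_q, renyi_alpha = renyi_alpha,
                 spectrum_estimator = match.arg(spectrum_estimator)),
            class = "wpd_config")
}

## One periodized analysis step: x (even length) -> list(low, high), each
## of length n/2. Orthonormal, so energy is conserved exactly.
dwt_step <- function(x, h = SYM8_DEC_LO) {
  n <- length(x)
  L <- length(h)
  g <- rev(h) * (-1)^(seq_len(L) - 1)      # quadrature mirror high-pass
  wrap <- ((n:(n + L - 2)) %% n) + 1       # circular continuation, L-1 samples
  ext <- c(x, x[wrap])
  zl <- stats::filter(ext, rev(h), method = "convolution", sides = 1)
  zh <- stats::filter(ext, rev(g), method = "convolution", sides = 1)
  cl <- zl[(L:(n + L - 1))]
  ch <- zh[(L:(n + L - 1))]
  odd <- seq(1, n, by = 2)
  list(low = as.numeric(cl[odd]), high = as.numeric(ch[odd]))
}

## Natural (tree) order node index of the terminal band at frequency
## position f (both 0-based): binary-reflected Gray code.
wpd_frequency_order <- function(levels) {
  f <- 0:(2^levels - 1)
  bitwXor(f, bitwShiftR(f, 1)) + 1L        # 1-based natural indices
}

#' Wavelet packet sub-band coefficients, frequency ordered
#'
#' Decomposes a segment into the `2^levels` terminal packet nodes of the
#' sym8 tree and reorders them from natural (tree) order to ascending
#' frequency order, so band `b` nominally covers
#' `[(b-1), b) * fs / 2^(levels+1)` Hz. The input is trimmed to a multiple
#' of `2^levels` samples for the periodized transform.
#'
#' @param samples numeric vector, length >= `2^levels`.
#' @param config a [wpd_config()].
#' @return list of `2^levels` coefficient vectors, ascending frequency.
#' @export
wpd_subbands <- function(samples, config = wpd_config()) {
  levels <- config$levels
  block <- 2^levels
  n <- (length(samples) %/% block) * block
  if (n < block) stopf("segment shorter than 2^levels = %d samples", block)
  x <- samples[seq_len(n)]
  nodes <- list(x)
  for (l in seq_len(levels)) {
    nxt <- vector("list", 2 * length(nodes))
    for (i in seq_along(nodes)) {
      s <- dwt_step(nodes[[i]])
      nxt[[2 * i - 1]] <- s$low
      nxt[[2 * i]] <- s$high
    }
    nodes <- nxt
  }
  nodes[wpd_frequency_order(levels)]
}

#' Nominal sub-band width
#'
#' @param fs sampling rate of the analyzed (decimated) signal, Hz.
#' @param levels decomposition depth.
#' @return band width in Hz (`fs / 2^(levels+1)`).
#' @export
wpd_band_width <- function(fs, levels = 5L) fs / 2^(levels + 1)

#' Human-readable frequency label of an analysis band
#'
#' @param band band index (1-based, frequency order).
#' @param fs analyzed sampling rate, Hz.
#' @param levels decomposition depth.
#' @return string such as `"0-172"` (Hz, integer-truncated edges).
#' @export
band_label_hz <- function(band, fs = 11025, levels = 5L) {
  w <- wpd_band_width(fs, levels)
  sprintf("%d-%d", round((band - 1) * w), floor(band * w))
}
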