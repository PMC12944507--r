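## ---------------------------------------------------------------------------
## Per-band acoustic descriptors and the 640-dimensional subject feature
## vector: 16 descriptors x 10 bands x 4 maneuvers, cycle-averaged within
## maneuver and concatenated in MI, ME, NI, NE order.
## ---------------------------------------------------------------------------

MANEUVERS <- c("MI", "ME", "NI", "NE")

#' Descriptor names in canonical order
#'
#' Statistical (mean, variance, std, energy, median), higher-order
#' (skewness, kurtosis), temporal (zero-crossing rate), spectral
#' (centroid, spread, skewness, kurtosis, entropy) and complexity
#' (Shannon, Tsallis, Renyi entropies).
#'
#' @return character vector of length 16.
#' @export
descriptor_names <- function() {
  c("mean", "variance", "std", "energy", "median",
    "skewness", "kurtosis", "zcr",
    "spectral_centroid", "spectral_spread", "spectral_skewness",
    "spectral_kurtosis", "spectral_entropy",
    "shannon_entropy", "tsallis_entropy", "renyi_entropy")
}

#' Compute the 16 descriptors of one sub-band
#'
#' Moments and median are computed on the coefficient sequence; spectral
#' descriptors on its normalized periodogram (frequency grid up to
#' `band_fs / 2`); complexity entropies on the normalized
#' squared-coefficient distribution. Degenerate bands (zero energy or a
#' single coefficient) return 0 for the otherwise undefined descriptors.
#'
#' @param coeffs numeric vector of band coefficients.
#' @param band_fs effective sampling rate of the coefficient sequence
#'   (`fs / 2^levels`), Hz.
#' @param tsallis_q,renyi_alpha entropy orders.
#' @param spectral_signal optional alternative signal (e.g. the
#'   band-limited reconstruction) on which the spectral descriptors are
#'   computed instead of the coefficients.
#' @param spectral_fs sampling rate of `spectral_signal`, Hz.
#' @return named numeric vector of length 16 in [descriptor_names()] order.
#' @export
band_descriptors <- function(coeffs, band_fs, tsallis_q = 2, renyi_alpha = 2,
                             spectral_signal = NULL, spectral_fs = band_fs) {
  stopifnot(length(coeffs) >= 1)
  x <- coeffs
  n <- length(x)
  m <- mean(x)
  v <- if (n > 1) stats::var(x) else 0
  energy <- sum(x^2)
  med <- stats::median(x)
  xc <- x - m
  m2 <- mean(xc^2)
  skew <- if (m2 > 0) mean(xc^3) / m2^1.5 else 0
  kurt <- if (m2 > 0) mean(xc^4) / m2^2 else 0
  zcr <- if (n > 1) sum(x[-1] * x[-n] < 0) / (n - 1) else 0

  ## spectral descriptors of the (coefficient or reconstruction) periodogram
  sx <- if (is.null(spectral_signal)) x else spectral_signal
  sfs <- if (is.null(spectral_signal)) band_fs else spectral_fs
  ns <- length(sx)
  if (energy > 0 && ns > 1) {
    P <- abs(fft(sx))^2
    half <- floor(ns / 2) + 1
    p <- P[1:half]
    freq <- (0:(half - 1)) * sfs / ns
    ps <- sum(p)
    p <- if (ps > 0) p / ps else rep(1 / half, half)
    centroid <- sum(freq * p)
    spread <- sqrt(sum((freq - centroid)^2 * p))
    if (spread > 0) {
      sskew <- sum(((freq - centroid) / spread)^3 * p)
      skurt <- sum(((freq - centroid) / spread)^4 * p)
    } else sskew <- skurt <- 0
    pp <- p[p > 0]
    sentropy <- -sum(pp * log(pp))
  } else centroid <- spread <- sskew <- skurt <- sentropy <- 0

  ## complexity entropies of the normalized squared coefficients
  if (energy > 0) {
    q <- x^2 / energy
    qq <- q[q > 0]
    shannon <- -sum(qq * log(qq))
    tsallis <- (1 - sum(qq^tsallis_q)) / (tsallis_q - 1)
    renyi <- log(sum(qq^renyi_alpha)) / (1 - renyi_alpha)
  } else shannon <- tsallis <- renyi <- 0

  stats::setNames(
    c(m, v, sqrt(v), energy, med, skew, kurt, zcr,
      centroid, spread, sskew, skurt, sentropy, shannon, tsallis, renyi),
    descriptor_names())
}

#' Map (maneuver, band, descriptor) to the flat feature index
#'
#' `index = (maneuver - 1) * 160 + (band - 1) * 16 + descriptor`, a
#' bijection onto 1..640 with maneuvers ordered MI, ME, NI, NE.
#'
#' @param maneuver `"MI"`, `"ME"`, `"NI"`, `"NE"` or 1..4.
#' @param band band index 1..10.
#' @param descriptor descriptor index 1..16 (see [descriptor_names()]).
#' @return integer feature index in 1..640.
#' @export
feature_index <- function(maneuver, band, descriptor) {
  if (is.character(maneuver)) maneuver <- match(maneuver, MANEUVERS)
  if (is.character(descriptor)) descriptor <- match(descriptor, descriptor_names())
  if (anyNA(maneuver) || any(maneuver < 1 | maneuver > 4))
    stopf("maneuver out of range")
  if (any(band < 1 | band > 10)) stopf("band out of range")
  if (anyNA(descriptor) || any(descriptor < 1 | descriptor > 16))
    stopf("descriptor out of range")
  as.integer((maneuver - 1) * 160 + (band - 1) * 16 + descriptor)
}

#' Inverse of [feature_index()]
#'
#' @param index feature index in 1..640.
#' @param fs recording sampling rate (for the Hz band label).
#' @return data.frame with `index`, `maneuver`, `band`, `descriptor`,
#'   `descriptor_name`, `band_hz`.
#' @export
feature_name <- function(index, fs = 44100) {
  if (any(index < 1 | index > 640)) stopf("feature index out of range")
  i0 <- index - 1L
  man <- i0 %/% 160L + 1L
  band <- (i0 %% 160L) %/% 16L + 1L
  desc <- i0 %% 16L + 1L
  data.frame(index = as.integer(index), maneuver = MANEUVERS[man],
             band = as.integer(band), descriptor = as.integer(desc),
             descriptor_name = descriptor_names()[desc],
             band_hz = band_label_hz(band, fs / 4),
             stringsAsFactors = FALSE)
}

## 160-vector (10 bands x 16 descriptors, band-major) of one conditioned
## segment.
segment_features <- function(segment, config = wpd_config()) {
  bands <- wpd_subbands(segment$samples, config)
  band_fs <- segment$fs / 2^config$levels
  recon <- NULL
  if (config$spectrum_estimator == "reconstruction") {
    ## band-limited views of the segment at the original rate (FFT mask
    ## over each band's nominal support), used for spectral descriptors
    block <- 2^config$levels
    ntr <- (length(segment$samples) %/% block) * block
    xs <- segment$samples[seq_len(ntr)]
    X <- fft(xs)
    fgrid <- (seq_len(ntr) - 1) / ntr * segment$fs
    fgrid <- pmin(fgrid, segment$fs - fgrid)
    w <- wpd_band_width(segment$fs, config$levels)
    recon <- lapply(seq_len(config$n_bands_kept), function(b) {
      mask <- fgrid >= (b - 1) * w & fgrid < b * w
      Re(fft(X * mask, inverse = TRUE)) / ntr
    })
  }
  out <- numeric(config$n_bands_kept * 16L)
  for (b in seq_len(config$n_bands_kept)) {
    out[((b - 1) * 16 + 1):(b * 16)] <-
      band_descriptors(bands[[b]], band_fs, config$tsallis_q,
                       config$renyi_alpha,
                       spectral_signal = if (is.null(recon)) NULL else recon[[b]],
                       spectral_fs = segment$fs)
  }
  out
}

#' Subject feature vector from conditioned segments
#'
#' Computes the 160-dimensional descriptor block per breathing cycle,
#' averages cycles within each maneuver and concatenates the four
#' maneuver blocks (MI, ME, NI, NE) into the 640-dimensional acoustic
#' vector. Maneuvers without cycles are `NA` and flagged in
#' `missing_mask`.
#'
#' @param segments list of conditioned segments (each with `samples`,
#'   `fs`, `maneuver`) for one subject.
#' @param config a [wpd_config()].
#' @return list with `acoustic` (numeric 640), `missing_mask` (named
#'   logical 4), `n_cycles` (named integer 4).
#' @export
subject_features <- function(segments, config = wpd_config()) {
  mans <- vapply(segments, `[[`, character(1), "maneuver")
  acoustic <- rep(NA_real_, 4 * config$n_bands_kept * 16L)
  n_cycles <- stats::setNames(integer(4), MANEUVERS)
  for (mi in seq_along(MANEUVERS)) {
    idx <- which(mans == MANEUVERS[mi])
    n_cycles[mi] <- length(idx)
    if (length(idx) == 0) next
    block <- rowMeans(vapply(segments[idx], segment_features,
                             numeric(config$n_bands_kept * 16L),
                             config = config))
    acoustic[((mi - 1) * 160 + 1):((mi - 1) * 160 + 160)] <- block
  }
  list(acoustic = acoustic,
       missing_mask = stats::setNames(n_cycles == 0, MANEUVERS),
       n_cycles = n_cycles)
}

#' Fit a z-score scaler on a training matrix
#'
#' @param X numeric matrix (subjects x features).
#' @return list with `center`, `scale` (sample sd; zero-variance columns
#'   get scale 1 with a warning).
#' @export
zscore_fit <- function(X) {
  stopifnot(nrow(X) >= 2)
  center <- colMeans(X)
  scale <- apply(X, 2, stats::sd)
  bad <- !is.finite(scale) | scale == 0
  if (any(bad)) {
    warning(sprintf("%d zero-variance column(s); scale set to 1", sum(bad)))
    scale[bad] <- 1
  }
  list(center = center, scale = scale)
}

#' Apply a fitted z-score scaler
#'
#' @param scaler from [zscore_fit()].
#' @param X numeric matrix with the same columns.
#' @return standardized matrix.
#' @export
zscore_apply <- function(scaler, X) {
  sweep(sweep(X, 2, scaler$center, "-"), 2, scaler$scale, "/")
}
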