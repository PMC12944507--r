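## ---------------------------------------------------------------------------
## Preprocessing: log-variance envelope segmentation of recordings into
## inspiration/expiration phases, per-phase SNR against the silent period,
## subject gating, and the per-phase conditioning chain (anti-alias band-pass
## -> decimate x4 -> stationary 50% extraction -> 75-3500 Hz band-pass ->
## 8-sample moving average -> standard-deviation normalization).
## ---------------------------------------------------------------------------

#' Preprocessing configuration
#'
#' @param snr_min_linear minimum per-phase linear SNR (phase power over
#'   silent power); 2 corresponds to roughly 3 dB.
#' @param min_phases_per_maneuver subjects with fewer retained phases in
#'   any maneuver are excluded.
#' @param envelope_window_ms log-variance envelope window.
#' @param envelope_overlap fractional window overlap.
#' @param antialias_band_hz band edges of the anti-aliasing band-pass.
#' @param antialias_order Butterworth design order of the anti-alias filter.
#' @param clean_band_hz band edges of the post-extraction band-pass.
#' @param clean_order Butterworth design order of the cleaning filter.
#' @param decimation decimation factor after anti-alias filtering.
#' @param ma_window_samples moving-average window (samples).
#' @param min_phase_s minimum phase duration retained by segmentation.
#' @return a `preprocess_config` list.
#' @export
preprocess_config <- function(snr_min_linear = 2,
                              min_phases_per_maneuver = 2L,
                              envelope_window_ms = 30,
                              envelope_overlap = 0.5,
                              antialias_band_hz = c(75, 5000),
                              antialias_order = 4L,
                              clean_band_hz = c(75, 3500),
                              clean_order = 6L,
                              decimation = 4L,
                              ma_window_samples = 8L,
                              min_phase_s = 0.25) {
  stopifnot(decimation >= 1, snr_min_linear >= 0,
            envelope_overlap >= 0, envelope_overlap < 1)
  structure(list(snr_min_linear = snr_min_linear,
                 min_phases_per_maneuver = as.integer(min_phases_per_maneuver),
                 envelope_window_ms = envelope_window_ms,
                 envelope_overlap = envelope_overlap,
                 antialias_band_hz = antialias_band_hz,
                 antialias_order = as.integer(antialias_order),
                 clean_band_hz = clean_band_hz,
                 clean_order = as.integer(clean_order),
                 decimation = as.integer(decimation),
                 ma_window_samples = as.integer(ma_window_samples),
                 min_phase_s = min_phase_s),
            class = "preprocess_config")
}

#' Log-variance envelope
#'
#' Log of the sample variance in sliding windows (default 30 ms, 50%
#' overlap). A relative epsilon floor (1e-12 of the overall signal power)
#' keeps all-constant windows finite.
#'
#' @param samples numeric vector.
#' @param fs sampling rate, Hz.
#' @param window_ms window length, ms.
#' @param overlap fractional overlap in `[0, 1)`.
#' @return list with `envelope` (log variance per frame), `centers`
#'   (frame center sample indices), `starts`, `ends`, `hop`, `window`.
#' @export
log_variance_envelope <- function(samples, fs, window_ms = 30, overlap = 0.5) {
  w <- max(2L, round(fs * window_ms / 1000))
  if (length(samples) < w) stopf("signal shorter than one envelope window")
  hop <- max(1L, round(w * (1 - overlap)))
  starts <- seq(1L, length(samples) - w + 1L, by = hop)
  cs <- cumsum(c(0, samples))
  cs2 <- cumsum(c(0, samples^2))
  s1 <- cs[starts + w] - cs[starts]
  s2 <- cs2[starts + w] - cs2[starts]
  v <- pmax((s2 - s1^2 / w) / (w - 1), 0)
  eps <- 1e-12 * max(mean(samples^2), 1e-30)
  list(envelope = log(v + eps), centers = starts + (w - 1) / 2,
       starts = starts, ends = starts + w - 1L, hop = hop, window = w)
}

#' Segment a recording into breathing phases
#'
#' Thresholds the log-variance envelope at the midpoint between the
#' silent-period median envelope and the recording's 95th-percentile
#' envelope; contiguous supra-threshold runs longer than `min_phase_s`
#' become phases, labeled by alternation starting with inspiration. The
#' first run after the silent period is flagged `adjacent_to_silence`.
#'
#' @param recording a `breath_recording` (needs `samples`, `fs`,
#'   `silent_span`, `route`).
#' @param config a [preprocess_config()].
#' @return list of phase lists (`samples`, `fs`, `span`, `maneuver`,
#'   `phase`, `adjacent_to_silence`, `snr_linear` = NA); empty if no run
#'   exceeds the threshold.
#' @export
segment_phases <- function(recording, config = preprocess_config()) {
  env <- log_variance_envelope(recording$samples, recording$fs,
                               config$envelope_window_ms, config$envelope_overlap)
  sil <- recording$silent_span
  in_sil <- env$starts >= sil[1] & env$ends <= sil[2]
  if (!any(in_sil)) stopf("recording has no silent span coverage")
  thr <- (stats::median(env$envelope[in_sil]) +
            stats::quantile(env$envelope, 0.95, names = FALSE)) / 2
  above <- env$envelope > thr
  r <- rle(above)
  ends_idx <- cumsum(r$lengths)
  starts_idx <- ends_idx - r$lengths + 1L
  keep <- which(r$values)
  phases <- list()
  for (k in keep) {
    a <- env$starts[starts_idx[k]]
    b <- env$ends[ends_idx[k]]
    if ((b - a + 1) / recording$fs < config$min_phase_s) next
    if (b <= sil[2]) next                       # inside the breath-hold
    phases[[length(phases) + 1L]] <- list(span = c(a, b))
  }
  out <- vector("list", length(phases))
  for (i in seq_along(phases)) {
    ph_type <- if (i %% 2 == 1) "inspiration" else "expiration"
    sp <- phases[[i]]$span
    out[[i]] <- list(
      subject_id = recording$subject_id,
      samples = recording$samples[sp[1]:sp[2]],
      fs = recording$fs, span = sp,
      phase = ph_type,
      maneuver = maneuver_code(recording$route, ph_type),
      adjacent_to_silence = (i == 1L),
      snr_linear = NA_real_)
  }
  out
}

#' Per-phase signal-to-noise ratio
#'
#' Linear power ratio of the phase over the silent (breath-hold) period.
#'
#' @param phase_samples numeric vector of a breathing phase.
#' @param silent_samples numeric vector of the silent period.
#' @return linear SNR (dimensionless).
#' @export
estimate_snr <- function(phase_samples, silent_samples) {
  if (length(silent_samples) == 0) stopf("empty silent segment")
  p_sil <- mean(silent_samples^2)
  if (p_sil == 0) stopf("degenerate silent segment (zero power)")
  mean(phase_samples^2) / p_sil
}

#' Gate a subject's phases by SNR and minimum phase counts
#'
#' Drops phases below `snr_min_linear` and flags the subject excluded if
#' any of the four maneuvers retains fewer than
#' `min_phases_per_maneuver` phases.
#'
#' @param phases list of phase lists with `snr_linear` and `maneuver` set.
#' @param config a [preprocess_config()].
#' @param maneuvers maneuvers the subject is required to cover.
#' @return list with `kept` (phases), `excluded` (flag), `reason`.
#' @export
gate_subject <- function(phases, config = preprocess_config(),
                         maneuvers = c("MI", "ME", "NI", "NE")) {
  snr <- vapply(phases, `[[`, numeric(1), "snr_linear")
  if (anyNA(snr)) stopf("phases must have snr_linear set before gating")
  kept <- phases[snr >= config$snr_min_linear]
  counts <- table(factor(vapply(kept, `[[`, character(1), "maneuver"),
                         levels = maneuvers))
  if (any(counts < config$min_phases_per_maneuver)) {
    bad <- names(counts)[counts < config$min_phases_per_maneuver]
    return(list(kept = kept, excluded = TRUE,
                reason = sprintf("insufficient phases (%s)",
                                 paste(bad, collapse = ","))))
  }
  list(kept = kept, excluded = FALSE, reason = NA_character_)
}

## Cascaded zero-phase Butterworth band-pass: high-pass and low-pass
## sections applied separately for numerical robustness at very low
## normalized corner frequencies.
bandpass_zerophase <- function(samples, fs, band, order) {
  hp <- signal::butter(order, band[1] / (fs / 2), type = "high")
  lp <- signal::butter(order, band[2] / (fs / 2), type = "low")
  y <- signal::filtfilt(hp, samples)
  signal::filtfilt(lp, y)
}

#' Anti-alias filter and decimate
#'
#' Zero-phase Butterworth band-pass (default 75-5000 Hz, order 4) followed
#' by decimation (default x4: 44100 -> 11025 Hz).
#'
#' @param samples numeric vector.
#' @param fs input sampling rate, Hz.
#' @param config a [preprocess_config()].
#' @return list with `samples` and `fs` (= input fs / decimation).
#' @export
antialias_downsample <- function(samples, fs, config = preprocess_config()) {
  new_nyq <- fs / (2 * config$decimation)
  if (config$antialias_band_hz[2] > new_nyq)
    stopf("anti-alias band edge %g Hz >= decimated Nyquist %g Hz",
          config$antialias_band_hz[2], new_nyq)
  y <- bandpass_zerophase(samples, fs, config$antialias_band_hz,
                          config$antialias_order)
  list(samples = y[seq(1, length(y), by = config$decimation)],
       fs = fs / config$decimation)
}

#' Extract the stationary portion of a phase
#'
#' The half-duration window centered on the maximum of the log-variance
#' envelope (ties resolved to the earliest frame); the window shifts
#' inward at the signal edges so its length is preserved.
#'
#' @param samples numeric vector (typically decimated phase samples).
#' @param fs sampling rate, Hz.
#' @param config a [preprocess_config()].
#' @return numeric vector of length `floor(length(samples) / 2)`.
#' @export
extract_stationary <- function(samples, fs, config = preprocess_config()) {
  n <- length(samples)
  w <- max(2L, round(fs * config$envelope_window_ms / 1000))
  if (n < 2 * w) stopf("phase too short for stationary extraction")
  env <- log_variance_envelope(samples, fs, config$envelope_window_ms,
                               config$envelope_overlap)
  peak <- round(env$centers[which.max(env$envelope)])
  len <- floor(n / 2)
  start <- peak - floor(len / 2)
  start <- min(max(start, 1L), n - len + 1L)
  samples[start:(start + len - 1L)]
}

#' Band-pass, smooth and normalize a stationary segment
#'
#' Zero-phase Butterworth band-pass (default 75-3500 Hz, order 6), then an
#' 8-sample centered moving average (intra-segment smoothing), then
#' division by the segment's (sample) standard deviation, producing a
#' unit-variance segment comparable across subjects.
#'
#' @param samples numeric vector.
#' @param fs sampling rate, Hz.
#' @param config a [preprocess_config()].
#' @return list with `samples` (sd exactly 1) and `fs`.
#' @export
normalize_segment <- function(samples, fs, config = preprocess_config()) {
  y <- bandpass_zerophase(samples, fs, config$clean_band_hz, config$clean_order)
  y <- moving_average(y, config$ma_window_samples)
  s <- stats::sd(y)
  if (!is.finite(s) || s <= 0) stopf("degenerate segment (zero variance)")
  list(samples = y / s, fs = fs)
}

#' Mean power spectrum of a maneuver's segments
#'
#' Welch-averaged periodogram (Hann windows, 50% overlap) per segment,
#' then mean and standard error across segments, in dB. Optionally flags
#' harmonic comb noise.
#'
#' @param segments list of numeric vectors (same fs).
#' @param fs sampling rate, Hz.
#' @param nfft Welch window length (samples).
#' @param detect_comb if TRUE, run the harmonic-comb heuristic.
#' @return list with `freq`, `mean_db`, `sem_db`, and `harmonic_flag` if
#'   requested.
#' @export
mean_psd <- function(segments, fs, nfft = 256L, detect_comb = FALSE) {
  stopifnot(length(segments) >= 1)
  psd_one <- function(x) {
    n <- length(x)
    if (n < nfft) nfft <- 2^floor(log2(n))
    hop <- nfft / 2
    starts <- seq(1, n - nfft + 1, by = hop)
    win <- 0.5 * (1 - cos(2 * pi * seq_len(nfft) / (nfft + 1)))
    acc <- numeric(nfft / 2 + 1)
    for (s in starts) {
      seg <- x[s:(s + nfft - 1)] * win
      P <- abs(fft(seg))^2 / (sum(win^2) * fs)
      acc <- acc + P[1:(nfft / 2 + 1)]
    }
    acc / length(starts)
  }
  mats <- lapply(segments, psd_one)
  nmin <- min(lengths(mats))
  m <- do.call(rbind, lapply(mats, function(p) p[1:nmin]))
  freq <- (0:(nmin - 1)) * fs / (2 * (nmin - 1))
  db <- 10 * log10(pmax(m, 1e-300))
  out <- list(freq = freq,
              mean_db = colMeans(db),
              sem_db = apply(db, 2, stats::sd) / sqrt(nrow(db)))
  if (detect_comb) out$harmonic_flag <- detect_harmonic_comb(freq, out$mean_db)
  out
}

#' Harmonic comb heuristic
#'
#' Scans candidate fundamentals (default 60-400 Hz) and flags the spectrum
#' if at least `min_harmonics` harmonics all sit `min_excess_db` above
#' their local spectral neighborhood.
#'
#' @param freq frequency grid, Hz.
#' @param psd_db spectrum in dB.
#' @param f0_range candidate fundamental range, Hz.
#' @param min_harmonics minimum number of harmonics required.
#' @param min_excess_db required mean peak excess over the neighborhood.
#' @return TRUE if a comb is detected.
#' @export
detect_harmonic_comb <- function(freq, psd_db, f0_range = c(60, 400),
                                 min_harmonics = 4L, min_excess_db = 6) {
  df <- freq[2] - freq[1]
  f0s <- seq(max(f0_range[1], 2 * df), f0_range[2], by = df)
  fmax <- max(freq)
  for (f0 in f0s) {
    harmonics <- seq(f0, fmax * 0.9, by = f0)
    if (length(harmonics) < min_harmonics) next
    harmonics <- harmonics[seq_len(min(length(harmonics), 8L))]
    excess <- vapply(harmonics, function(h) {
      i <- which.min(abs(freq - h))
      nb <- freq > h - 3 * f0 / 4 & freq < h + 3 * f0 / 4 &
        abs(freq - h) > f0 / 4
      if (!any(nb)) return(0)
      max(psd_db[pmax(i - 1, 1):pmin(i + 1, length(psd_db))]) -
        stats::median(psd_db[nb])
    }, numeric(1))
    if (sum(excess >= min_excess_db) >= min_harmonics &&
        mean(excess) >= min_excess_db) return(TRUE)
  }
  FALSE
}

#' Full per-recording preprocessing
#'
#' Segments a recording, computes per-phase SNR against the silent period
#' and returns phases with SNR attached (gating is applied per subject
#' across both routes with [gate_subject()]).
#'
#' @param recording a `breath_recording`.
#' @param config a [preprocess_config()].
#' @return list of phases with `snr_linear` filled in.
#' @export
preprocess_recording <- function(recording, config = preprocess_config()) {
  phases <- segment_phases(recording, config)
  silent <- recording$samples[recording$silent_span[1]:recording$silent_span[2]]
  for (i in seq_along(phases)) {
    phases[[i]]$snr_linear <- estimate_snr(phases[[i]]$samples, silent)
  }
  phases
}

#' Condition one gated phase into a normalized stationary segment
#'
#' Applies the chain: anti-alias band-pass + decimation, stationary 50%
#' extraction, cleaning band-pass, moving average, sd normalization.
#'
#' @param phase a phase list (from [segment_phases()]).
#' @param config a [preprocess_config()].
#' @return list with `samples`, `fs`, `maneuver`, `subject_id`; or `NULL`
#'   if the phase is too short after decimation.
#' @export
condition_phase <- function(phase, config = preprocess_config()) {
  dec <- antialias_downsample(phase$samples, phase$fs, config)
  w <- max(2L, round(dec$fs * config$envelope_window_ms / 1000))
  if (length(dec$samples) < 2 * w) return(NULL)
  stat <- extract_stationary(dec$samples, dec$fs, config)
  seg <- normalize_segment(stat, dec$fs, config)
  list(samples = seg$samples, fs = seg$fs,
       maneuver = phase$maneuver, subject_id = phase$subject_id)
}
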