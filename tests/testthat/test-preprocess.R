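test_that("log-variance envelope matches closed forms", {
  set.seed(3)
  fs <- 8000
  ## standardized white noise: log variance near 0 per frame
  env <- log_variance_envelope(rnorm(fs), fs)
  expect_lt(abs(mean(env$envelope)), 0.05)
  ## silence floors at log(eps) without -Inf
  env0 <- log_variance_envelope(numeric(fs), fs)
  expect_true(all(is.finite(env0$envelope)))
  expect_equal(stats::sd(env0$envelope), 0)
  ## amplitude step x10 -> envelope step of log(100)
  x <- c(rnorm(fs), 10 * rnorm(fs))
  envs <- log_variance_envelope(x, fs)
  first <- envs$envelope[envs$ends <= fs]
  second <- envs$envelope[envs$starts > fs]
  expect_equal(mean(second) - mean(first), log(100), tolerance = 0.05)
  expect_error(log_variance_envelope(rnorm(10), fs), "shorter")
})

test_that("segmentation recovers planted bursts and labels by alternation", {
  set.seed(4)
  fs <- 8000
  floor_sd <- 0.01
  n_sil <- 1.5 * fs
  spans <- list()
  x <- rnorm(n_sil, 0, floor_sd)
  amp <- floor_sd * sqrt(10^(15 / 10))      # 15 dB bursts
  for (b in seq_len(10)) {
    x <- c(x, rnorm(0.4 * fs, 0, floor_sd))
    spans[[b]] <- c(length(x) + 1, length(x) + 0.8 * fs)
    x <- c(x, rnorm(0.8 * fs, 0, amp))
  }
  x <- c(x, rnorm(0.4 * fs, 0, floor_sd))
  rec <- structure(list(subject_id = "T", route = "nose", samples = x,
                        fs = fs, silent_span = c(1L, as.integer(n_sil))),
                   class = "breath_recording")
  ph <- segment_phases(rec)
  expect_length(ph, 10)
  for (i in seq_along(ph))
    expect_gte(span_iou(ph[[i]]$span, spans[[i]]), 0.7)
  expect_equal(vapply(ph, `[[`, character(1), "phase"),
               rep(c("inspiration", "expiration"), 5))
  expect_equal(vapply(ph, `[[`, character(1), "maneuver"),
               rep(c("NI", "NE"), 5))
  expect_true(ph[[1]]$adjacent_to_silence)
  expect_false(any(vapply(ph[-1], `[[`, logical(1), "adjacent_to_silence")))

  ## pure stationary noise: nothing above threshold
  rec0 <- rec
  rec0$samples <- rnorm(length(x), 0, floor_sd)
  expect_length(segment_phases(rec0), 0)

  ## single burst is labeled inspiration
  y <- c(rnorm(n_sil, 0, floor_sd), rnorm(0.5 * fs, 0, floor_sd),
         rnorm(0.6 * fs, 0, amp), rnorm(0.5 * fs, 0, floor_sd))
  rec1 <- rec
  rec1$samples <- y
  ph1 <- segment_phases(rec1)
  expect_length(ph1, 1)
  expect_equal(ph1[[1]]$phase, "inspiration")
})

test_that("SNR estimation is a linear power ratio", {
  set.seed(5)
  sil <- rnorm(5000)
  phase <- rnorm(5000, 0, sqrt(2) * stats::sd(sil))
  expect_equal(estimate_snr(phase, sil), 2, tolerance = 0.1)  # about 3 dB
  expect_equal(estimate_snr(rnorm(5000), sil), 1, tolerance = 0.1)
  expect_equal(estimate_snr(2 * phase, sil) / estimate_snr(phase, sil), 4,
               tolerance = 1e-12)
  expect_error(estimate_snr(phase, numeric(0)), "empty")
  expect_error(estimate_snr(phase, numeric(10)), "zero power")
})

test_that("subject gating drops weak phases and flags sparse maneuvers", {
  mk <- function(man, snr) list(maneuver = man, snr_linear = snr,
                                samples = 1, fs = 1)
  phases <- c(
    lapply(c(1.5, 3, 4), mk, man = "MI"),
    lapply(c(2, 2.5), mk, man = "ME"),
    lapply(c(5, 6), mk, man = "NI"),
    lapply(c(2, 9), mk, man = "NE"))
  g <- gate_subject(phases)
  expect_false(g$excluded)
  expect_equal(sum(vapply(g$kept, `[[`, character(1), "maneuver") == "MI"), 2)

  weak <- c(lapply(c(1.5, 1.9), mk, man = "MI"),
            lapply(c(3, 3), mk, man = "ME"),
            lapply(c(3, 3), mk, man = "NI"),
            lapply(c(3, 3), mk, man = "NE"))
  gw <- gate_subject(weak)
  expect_true(gw$excluded)
  expect_match(gw$reason, "insufficient phases")
  ## gating is monotone in the SNR threshold
  strict <- gate_subject(phases, preprocess_config(snr_min_linear = 4))
  expect_lte(length(strict$kept), length(g$kept))
})

test_that("anti-alias decimation keeps band content and rejects low tones", {
  fs <- 44100
  t <- seq_len(fs) / fs
  cfg <- preprocess_config()
  out <- antialias_downsample(rnorm(fs), fs, cfg)
  expect_equal(out$fs, 11025)
  expect_equal(length(out$samples), ceiling(fs / 4))
  rms_after <- function(f) {
    y <- antialias_downsample(sin(2 * pi * f * t), fs, cfg)$samples
    sqrt(mean(y[500:10000]^2))
  }
  expect_gt(20 * log10(rms_after(1000) / rms_after(50)), 20)
  expect_error(
    antialias_downsample(rnorm(fs), 8000, cfg), "Nyquist")
})

test_that("stationary extraction centers on the envelope peak", {
  fs <- 8000
  set.seed(6)
  cfg <- preprocess_config()
  ## constant envelope (identical frame variance), argmax tie -> earliest
  ## frame -> leading half after edge clipping
  x <- rep(c(1, -1), 500)
  seg <- extract_stationary(x, fs, cfg)
  expect_length(seg, 500)
  expect_equal(seg, x[1:500])
  ## triangular envelope peaking at 70% -> window about 45%..95%
  n <- 4 * fs
  peak <- 0.7
  env <- 1 - abs(seq_len(n) / n - peak) / peak
  y <- env * rnorm(n)
  seg2 <- extract_stationary(y, fs, cfg)
  start_frac <- (match(seg2[1], y)) / n
  expect_lt(abs(start_frac - 0.45), 0.05)
  expect_error(extract_stationary(rnorm(100), fs, cfg), "too short")
})

test_that("normalization yields unit variance and is scale invariant", {
  set.seed(7)
  fs <- 11025
  x <- rnorm(fs)
  cfg <- preprocess_config()
  out <- normalize_segment(x, fs, cfg)
  expect_equal(stats::sd(out$samples), 1, tolerance = 1e-9)
  out7 <- normalize_segment(7 * x, fs, cfg)
  ## equality up to IIR filter floating-point accumulation
  expect_equal(out$samples, out7$samples, tolerance = 1e-5)
  ## the 75-3500 Hz filter rejects a 4 kHz tone against 1 kHz
  t <- seq_len(fs) / fs
  bp <- function(f) {
    y <- osascreen:::bandpass_zerophase(sin(2 * pi * f * t), fs,
                                        cfg$clean_band_hz, cfg$clean_order)
    sqrt(mean(y[1000:10000]^2))
  }
  expect_gt(20 * log10(bp(1000) / bp(4000)), 12)
  expect_error(normalize_segment(numeric(1000), fs, cfg), "degenerate")
})

test_that("mean power spectrum locates tones and flags harmonic combs", {
  fs <- 8000
  t <- seq_len(2 * fs) / fs
  tone <- sin(2 * pi * 500 * t)
  res <- mean_psd(list(tone), fs)
  expect_equal(res$freq[which.max(res$mean_db)], 500, tolerance = 20)
  ## white noise: roughly flat, no comb
  set.seed(8)
  segs <- lapply(1:5, function(i) rnorm(2 * fs))
  flat <- mean_psd(segs, fs, detect_comb = TRUE)
  expect_false(flat$harmonic_flag)
  iqr <- diff(stats::quantile(flat$mean_db[flat$freq > 100], c(0.05, 0.95)))
  expect_lt(iqr, 6)
  ## harmonic comb at multiples of 120 Hz fires the heuristic
  comb <- rowSums(vapply(1:8, function(k) sin(2 * pi * 120 * k * t),
                         numeric(length(t)))) + 0.05 * rnorm(length(t))
  withcomb <- mean_psd(list(comb), fs, detect_comb = TRUE)
  expect_true(withcomb$harmonic_flag)
})
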