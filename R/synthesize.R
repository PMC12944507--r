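## ---------------------------------------------------------------------------
## Audio synthesis: breath phases as amplitude-enveloped colored noise over a
## stationary background floor, with planted sub-band signatures and a
## log-normally scattered per-phase SNR. One recording per subject per route
## (nose / mouth), each starting with a breath-hold silent period.
## ---------------------------------------------------------------------------

## Analysis sub-band width in Hz: band b of the decimated (fs/4) signal
## spans [(b-1), b) * (fs/4)/64 = [(b-1), b) * fs/256.
band_width_hz <- function(fs) fs / 256

maneuver_code <- function(route, phase) {
  paste0(toupper(substr(route, 1, 1)), if (phase == "inspiration") "I" else "E")
}

## Per-(subject, maneuver) band gain profile in dB over the 10 analysis
## bands: a gently decaying base spectrum + per-subject jitter + planted
## signature shifts (in units of band_jitter_db).
subject_band_profile <- function(subject, maneuver, config) {
  base <- -1.5 * (0:9)
  jitter <- rnorm(10, 0, config$band_jitter_db)
  shift <- numeric(10)
  for (sig in config$signatures) {
    if (!is.null(sig$maneuver) && sig$maneuver != maneuver) next
    w <- 1
    if (!is.null(sig$label)) {
      w <- if (subject$label == sig$label) 1
           else if (subject$label == LABEL_GAP) 0.5 else 0
    }
    if (w > 0 && !is.null(sig$subgroup)) {
      pred <- subgroup_predicates()[[sig$subgroup]]
      if (!isTRUE(pred(subject))) w <- 0
    }
    if (w > 0) shift[sig$band] <- shift[sig$band] + w * sig$effect * config$band_jitter_db
  }
  base + jitter + shift
}

## Shape white noise to a piecewise band gain profile via FFT filtering,
## returning a unit-variance colored noise vector.
shape_noise <- function(n, fs, gains_db) {
  ## pad to a highly composite length so the FFT stays O(n log n)
  n_out <- n
  n <- stats::nextn(n, c(2, 3))
  x <- rnorm(n)
  X <- fft(x)
  freq <- (seq_len(n) - 1) / n * fs
  freq <- pmin(freq, fs - freq)           # two-sided -> |f|
  w <- band_width_hz(fs)
  g_db <- rep(-60, n)                      # default: far below the breath band
  band <- pmin(floor(freq / w) + 1, 11L)
  in10 <- band <= 10
  g_db[in10] <- gains_db[band[in10]]
  ## gentle continuation of the base decay between band 10 and 3.2 kHz
  mid <- freq > 10 * w & freq <= 3200
  g_db[mid] <- gains_db[10] - 6 * (freq[mid] - 10 * w) / (3200 - 10 * w)
  y <- Re(fft(X * 10^(g_db / 20), inverse = TRUE)) / n
  y <- y[seq_len(n_out)]
  y / sd(y)
}

#' Synthesize one tracheal breathing-sound recording
#'
#' Produces the maneuver protocol for one route: a leading breath-hold
#' (stationary noise only) followed by `cycles_per_maneuver` breathing
#' cycles, each an inspiration and an expiration burst of raised-cosine
#' enveloped colored noise whose 10-band spectrum carries the subject's
#' planted signatures. The per-phase linear SNR (phase power over silent
#' power) is drawn on the dB scale around `target_snr_db`.
#'
#' @param subject one cohort row.
#' @param route `"nose"` or `"mouth"`.
#' @param config a [synthesis_config()].
#' @return a `breath_recording` list: `subject_id`, `route`, `samples`,
#'   `fs`, `silent_span` (2-vector, samples), `truth_phase_spans`
#'   (data.frame `start`, `end`, `phase`).
#' @export
synthesize_recording <- function(subject, route, config) {
  stopifnot(route %in% c("nose", "mouth"))
  set.seed(derive_seed(config$seed, "audio", subject$subject_id, route))
  fs <- config$fs
  cv <- config$jitter_cv
  n_cycles <- config$cycles_per_maneuver

  profiles <- list(
    inspiration = subject_band_profile(subject, maneuver_code(route, "inspiration"), config),
    expiration = subject_band_profile(subject, maneuver_code(route, "expiration"), config)
  )

  ## recording-level SNR: the dataset-level spread is mostly between
  ## subjects; per-phase scatter around the recording level is smaller
  sd_within <- min(config$snr_within_sd_db, config$target_snr_db[["sd"]])
  sd_between <- sqrt(config$target_snr_db[["sd"]]^2 - sd_within^2)
  rec_snr_db <- rnorm(1, config$target_snr_db[["mean"]], sd_between)

  ## timeline
  n_sil <- round(config$silent_duration * fs)
  spans <- list()
  pos <- n_sil
  for (cy in seq_len(n_cycles)) {
    for (ph in c("inspiration", "expiration")) {
      dur <- runif(1, config$phase_duration_range[1], config$phase_duration_range[2])
      dur <- dur * max(0.5, 1 + cv * rnorm(1))
      np <- max(as.integer(round(dur * fs)), 32L)
      spans[[length(spans) + 1L]] <- list(start = as.integer(pos + 1L),
                                          end = as.integer(pos + np), phase = ph)
      pos <- pos + np
      pause <- config$inter_phase_pause * max(0.3, 1 + cv * rnorm(1))
      pos <- pos + round(pause * fs)
    }
  }
  n_total <- pos + round(0.5 * fs)

  noise_sd <- sqrt(config$noise_power)
  samples <- rnorm(n_total, 0, noise_sd)

  for (sp in spans) {
    np <- sp$end - sp$start + 1L
    gains <- profiles[[sp$phase]] + rnorm(10, 0, cv * config$band_jitter_db)
    burst <- shape_noise(np, fs, gains)
    ## raised-cosine (Tukey) envelope: sustained mid-phase airflow with
    ## cosine onset/offset ramps
    ramp <- max(2L, floor(0.15 * np))
    env <- rep(1, np)
    env[seq_len(ramp)] <- 0.5 * (1 - cos(pi * seq_len(ramp) / ramp))
    env[np + 1 - seq_len(ramp)] <- env[seq_len(ramp)]
    snr_db <- rnorm(1, rec_snr_db, sd_within)
    snr_lin <- max(10^(snr_db / 10), 1.1)
    ## phase power (signal + floor) / floor power = snr_lin
    p_signal <- (snr_lin - 1) * config$noise_power
    amp <- sqrt(p_signal / mean(env^2))
    samples[sp$start:sp$end] <- samples[sp$start:sp$end] + amp * env * burst
  }

  truth <- data.frame(
    start = vapply(spans, `[[`, integer(1), "start"),
    end = vapply(spans, `[[`, integer(1), "end"),
    phase = vapply(spans, `[[`, character(1), "phase"),
    stringsAsFactors = FALSE)

  structure(list(subject_id = subject$subject_id, route = route,
                 samples = samples, fs = fs,
                 silent_span = c(1L, n_sil), truth_phase_spans = truth),
            class = "breath_recording")
}

#' Write a cohort to disk (WAV audio + CSV metadata + manifest)
#'
#' @param records cohort data.frame.
#' @param recordings list of `breath_recording` objects (one per subject
#'   per route).
#' @param out_dir output directory (created if missing).
#' @param config the [synthesis_config()] used (hashed into the manifest).
#' @param bits WAV sample format (32 = IEEE float, lossless).
#' @return manifest path, invisibly.
#' @export
write_cohort <- function(records, recordings, out_dir, config = NULL, bits = 32L) {
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!ok || file.access(out_dir, 2) != 0) stopf("cannot write to %s", out_dir)
  ids <- vapply(recordings, `[[`, character(1), "subject_id")
  routes <- vapply(recordings, `[[`, character(1), "route")
  need <- expand.grid(subject_id = records$subject_id,
                      route = c("nose", "mouth"), stringsAsFactors = FALSE)
  have <- paste(ids, routes)
  if (!all(paste(need$subject_id, need$route) %in% have))
    stopf("one recording per subject per route is required")

  wavs <- character(length(recordings))
  truth <- vector("list", length(recordings))
  for (i in seq_along(recordings)) {
    r <- recordings[[i]]
    wavs[i] <- file.path(out_dir, sprintf("%s_%s.wav", r$subject_id, r$route))
    write_wav(r$samples, r$fs, wavs[i], bits = bits)
    truth[[i]] <- data.frame(subject_id = r$subject_id, route = r$route,
                             start_sample = r$truth_phase_spans$start,
                             end_sample = r$truth_phase_spans$end,
                             phase = r$truth_phase_spans$phase,
                             silent_start = r$silent_span[1],
                             silent_end = r$silent_span[2],
                             stringsAsFactors = FALSE)
  }
  meta <- records
  names(meta)[names(meta) == "neck_circumference"] <- "neck_cm"
  utils::write.csv(meta, file.path(out_dir, "metadata.csv"), row.names = FALSE)
  utils::write.csv(do.call(rbind, truth), file.path(out_dir, "truth.csv"),
                   row.names = FALSE)
  manifest <- list(
    n_subjects = nrow(records),
    seed = if (!is.null(config)) config$seed else NA,
    config_hash = if (!is.null(config)) object_hash(unclass(config)) else NA,
    files = basename(wavs))
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest_path)
}
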