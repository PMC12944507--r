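test_that("a recording carries the full maneuver protocol", {
  syn <- synthesis_config(class_counts = c("OSA" = 2, "non-OSA" = 1),
                          fs = 8000, silent_duration = 1.5,
                          phase_duration_range = c(0.6, 0.9), seed = 5)
  coh <- generate_cohort(syn)
  rec <- synthesize_recording(coh[1, ], "nose", syn)
  tr <- rec$truth_phase_spans
  expect_equal(nrow(tr), 10)  # five cycles = 5 inspirations + 5 expirations
  expect_equal(tr$phase, rep(c("inspiration", "expiration"), 5))
  ## silent span precedes all phases; spans disjoint and ordered
  expect_true(all(tr$start > rec$silent_span[2]))
  expect_true(all(diff(tr$start) > 0))
  expect_true(all(tr$start[-1] > tr$end[-nrow(tr)]))
  ## determinism: bit-identical samples for the same seed
  rec2 <- synthesize_recording(coh[1, ], "nose", syn)
  expect_identical(rec$samples, rec2$samples)
  ## different route differs
  recm <- synthesize_recording(coh[1, ], "mouth", syn)
  expect_false(identical(rec$samples, recm$samples))
})

test_that("realized phase SNR is calibrated to the target", {
  syn <- small_syn_config()
  coh <- generate_cohort(small_syn_config())
  snr_db <- c()
  for (i in seq_len(8)) {
    for (rt in c("nose", "mouth")) {
      r <- synthesize_recording(coh[i, ], rt, syn)
      sil <- r$samples[r$silent_span[1]:r$silent_span[2]]
      tr <- r$truth_phase_spans
      s <- vapply(seq_len(nrow(tr)), function(ti)
        estimate_snr(r$samples[tr$start[ti]:tr$end[ti]], sil), numeric(1))
      snr_db <- c(snr_db, 10 * log10(s))
    }
  }
  expect_gte(length(snr_db), 50)
  ## geometric mean (mean in dB) within 1 dB of the 10.7 dB target
  expect_lt(abs(mean(snr_db) - 10.7), 1)
})

test_that("planted signatures shift the targeted band energy", {
  sig <- list(spectral_signature(5, effect = 1.5, label = "OSA",
                                 maneuver = "NI"))
  syn <- synthesis_config(
    class_counts = c("OSA" = 12, "non-OSA" = 12),
    fs = 8000, cycles_per_maneuver = 2, silent_duration = 1.5,
    phase_duration_range = c(0.8, 1.2), signatures = sig,
    null_anthro = TRUE, seed = 31)
  coh <- generate_cohort(syn)
  pre <- small_pre_config()
  band5_log_energy <- function(subject) {
    rec <- synthesize_recording(subject, "nose", syn)
    phases <- preprocess_recording(rec, pre)
    insp <- Filter(function(p) p$maneuver == "NI", phases)
    segs <- Filter(Negate(is.null), lapply(insp, condition_phase, config = pre))
    if (length(segs) == 0) return(NA_real_)
    mean(vapply(segs, function(s) {
      bands <- wpd_subbands(s$samples)
      log(sum(bands[[5]]^2))
    }, numeric(1)))
  }
  e <- vapply(seq_len(nrow(coh)), function(i) band5_log_energy(coh[i, ]),
              numeric(1))
  osa <- e[coh$label == "OSA" & !is.na(e)]
  non <- e[coh$label == "non-OSA" & !is.na(e)]
  d <- (mean(osa) - mean(non)) /
    sqrt((stats::var(osa) + stats::var(non)) / 2)
  expect_gt(mean(osa), mean(non))
  ## standardized difference of the configured order (sampling error wide)
  expect_gt(d, 0.5)
})

test_that("write_cohort emits audio, tables and a seed-sensitive manifest", {
  syn <- synthesis_config(class_counts = c("OSA" = 1, "non-OSA" = 1),
                          fs = 4000, cycles_per_maneuver = 1,
                          silent_duration = 1,
                          phase_duration_range = c(0.5, 0.7), seed = 9)
  coh <- generate_cohort(syn)
  recs <- list()
  for (i in seq_len(nrow(coh)))
    for (rt in c("nose", "mouth"))
      recs[[length(recs) + 1]] <- synthesize_recording(coh[i, ], rt, syn)
  dir1 <- file.path(tempdir(), "cohort-a")
  manifest <- write_cohort(coh, recs, dir1, config = syn)
  expect_length(list.files(dir1, pattern = "\\.wav$"), 4)
  expect_length(list.files(dir1, pattern = "\\.csv$"), 2)
  expect_true(file.exists(manifest))
  ## WAV round trip
  back <- read_wav(file.path(dir1, sprintf("%s_nose.wav", coh$subject_id[1])))
  expect_equal(back$samples, recs[[1]]$samples, tolerance = 1e-6)
  ## manifest hash is seed-sensitive
  syn2 <- synthesis_config(class_counts = c("OSA" = 1, "non-OSA" = 1),
                           fs = 4000, cycles_per_maneuver = 1,
                           silent_duration = 1,
                           phase_duration_range = c(0.5, 0.7), seed = 10)
  h1 <- jsonlite::read_json(manifest)$config_hash
  dir2 <- file.path(tempdir(), "cohort-b")
  m2 <- write_cohort(generate_cohort(syn2), {
    coh2 <- generate_cohort(syn2)
    rs <- list()
    for (i in seq_len(nrow(coh2)))
      for (rt in c("nose", "mouth"))
        rs[[length(rs) + 1]] <- synthesize_recording(coh2[i, ], rt, syn2)
    rs
  }, dir2, config = syn2)
  expect_false(identical(h1, jsonlite::read_json(m2)$config_hash))
  ## a missing route is rejected
  expect_error(write_cohort(coh, recs[1:3], file.path(tempdir(), "cohort-c")),
               "per subject per route")
})
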