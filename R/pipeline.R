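## ---------------------------------------------------------------------------
## End-to-end orchestration: cohort -> (synthesize + preprocess + extract
## features, streamed per subject) -> evaluate, with YAML configuration,
## per-stage caching and a run manifest for reproducibility.
## ---------------------------------------------------------------------------

#' Extract the acoustic feature matrix for a cohort
#'
#' Streams subjects one at a time: obtains both route recordings,
#' segments them into phases, computes per-phase SNR, applies the
#' subject gate, conditions the retained phases and computes the
#' 640-dimensional cycle-averaged feature vector. Excluded subjects keep
#' a row of `NA` features and a recorded reason.
#'
#' @param cohort cohort data.frame.
#' @param recording_provider function `(subject_row, route)` returning a
#'   `breath_recording`; defaults to synthesizing with `syn_config`.
#' @param syn_config a [synthesis_config()] (used by the default
#'   provider).
#' @param pre_config a [preprocess_config()].
#' @param wpd_cfg a [wpd_config()].
#' @param verbose print per-subject progress.
#' @return list with `features` (subjects x 640 matrix), `meta` (cohort +
#'   `excluded`, `exclusion_reason`), `phase_log` (per-phase data.frame).
#' @export
extract_cohort_features <- function(cohort,
                                    recording_provider = NULL,
                                    syn_config = synthesis_config(),
                                    pre_config = preprocess_config(),
                                    wpd_cfg = wpd_config(),
                                    verbose = FALSE) {
  if (is.null(recording_provider)) {
    recording_provider <- function(subject, route)
      synthesize_recording(subject, route, syn_config)
  }
  n <- nrow(cohort)
  feats <- matrix(NA_real_, n, 640L)
  excluded <- logical(n)
  reason <- rep(NA_character_, n)
  phase_log <- list()
  for (i in seq_len(n)) {
    subject <- cohort[i, ]
    phases <- list()
    for (route in c("nose", "mouth")) {
      rec <- recording_provider(subject, route)
      phases <- c(phases, preprocess_recording(rec, pre_config))
    }
    if (length(phases)) {
      phase_log[[i]] <- data.frame(
        subject_id = subject$subject_id,
        maneuver = vapply(phases, `[[`, character(1), "maneuver"),
        start = vapply(phases, function(p) p$span[1], numeric(1)),
        end = vapply(phases, function(p) p$span[2], numeric(1)),
        snr_linear = vapply(phases, `[[`, numeric(1), "snr_linear"),
        kept = vapply(phases, `[[`, numeric(1), "snr_linear") >=
          pre_config$snr_min_linear,
        stringsAsFactors = FALSE)
    }
    gate <- gate_subject(phases, pre_config)
    if (gate$excluded) {
      excluded[i] <- TRUE
      reason[i] <- gate$reason
      if (verbose) message(subject$subject_id, ": excluded (", gate$reason, ")")
      next
    }
    segments <- Filter(Negate(is.null),
                       lapply(gate$kept, condition_phase, config = pre_config))
    sf <- subject_features(segments, wpd_cfg)
    feats[i, ] <- sf$acoustic
    if (any(sf$missing_mask)) {
      excluded[i] <- TRUE
      reason[i] <- sprintf("missing maneuver (%s)",
                           paste(names(which(sf$missing_mask)), collapse = ","))
    }
    if (verbose) message(subject$subject_id, ": ",
                         sum(!sf$missing_mask), "/4 maneuvers")
  }
  meta <- cohort
  meta$excluded <- excluded
  meta$exclusion_reason <- reason
  list(features = feats, meta = meta,
       phase_log = do.call(rbind, phase_log))
}

#' Run the full synthetic study in memory
#'
#' Generates a cohort, extracts features, evaluates the two-level
#' framework with outer cross-validation and (optionally) the global
#' non-stratified baseline on identical folds.
#'
#' @param syn_config a [synthesis_config()].
#' @param pre_config a [preprocess_config()].
#' @param wpd_cfg a [wpd_config()].
#' @param fw_config a [framework_config()].
#' @param seed integer seed for the evaluation harness.
#' @param baseline also run the global baseline.
#' @param verbose progress messages.
#' @return list with `cohort`, `features`, `meta` (gated subjects only),
#'   `evaluation`, `baseline`.
#' @export
run_study <- function(syn_config = synthesis_config(),
                      pre_config = preprocess_config(),
                      wpd_cfg = wpd_config(),
                      fw_config = framework_config(),
                      seed = 1L, baseline = TRUE, verbose = FALSE) {
  cohort <- generate_cohort(syn_config)
  ex <- extract_cohort_features(cohort, syn_config = syn_config,
                                pre_config = pre_config, wpd_cfg = wpd_cfg,
                                verbose = verbose)
  keep <- !ex$meta$excluded
  X <- ex$features[keep, , drop = FALSE]
  meta <- ex$meta[keep, , drop = FALSE]
  evaluation <- evaluate_framework(X, meta, fw_config, seed = seed)
  base <- NULL
  if (baseline) {
    is_gap <- meta$label == LABEL_GAP
    base <- global_baseline(X[!is_gap, , drop = FALSE],
                            meta[!is_gap, , drop = FALSE],
                            evaluation$folds, fw_config, seed = seed)
  }
  list(cohort = cohort, features = ex$features, meta = ex$meta,
       phase_log = ex$phase_log, evaluation = evaluation, baseline = base)
}

pipeline_defaults <- function() {
  list(
    seed = 1L,
    synthesis = list(
      n_osa = 149L, n_non_osa = 47L, n_gap = 32L, fs = 44100,
      cycles_per_maneuver = 5L, silent_duration = 3,
      phase_duration_min = 1.2, phase_duration_max = 2.0,
      snr_mean_db = 10.7, snr_sd_db = 4.2, signature_effect = 1.0,
      band_jitter_db = 2.0, jitter_cv = 0.10, null_anthro = FALSE),
    preprocess = list(
      snr_min_linear = 2, min_phases_per_maneuver = 2L,
      envelope_window_ms = 30, envelope_overlap = 0.5,
      antialias_low_hz = 75, antialias_high_hz = 5000, antialias_order = 4L,
      clean_low_hz = 75, clean_high_hz = 3500, clean_order = 6L,
      decimation = 4L, ma_window_samples = 8L, min_phase_s = 0.25),
    wpd = list(levels = 5L, n_bands_kept = 10L, tsallis_q = 2,
               renyi_alpha = 2),
    framework = list(
      B = 1000L, k_features = 7L, min_score = 0.01, outer_k = 4L,
      inner_repeats = 5L, threshold = 0.5, mode = "probability")
  )
}

merge_config <- function(defaults, user, path = "") {
  if (is.null(user)) return(defaults)
  for (key in names(user)) {
    if (!key %in% names(defaults))
      stopf("unknown configuration key: %s%s", path, key)
    if (is.list(defaults[[key]])) {
      defaults[[key]] <- merge_config(defaults[[key]], user[[key]],
                                      paste0(path, key, "."))
    } else {
      defaults[[key]] <- user[[key]]
    }
  }
  defaults
}

#' Load and validate a pipeline configuration
#'
#' Reads a YAML file (or takes a list), fills every unset key with the
#' study defaults (B = 1000, 7 stable features, SNR gate 2, 4 outer
#' folds, 3 x Nmin trees, threshold 0.5, ...) and rejects unknown keys.
#'
#' @param config path to a YAML file, a list, or `NULL` (all defaults).
#' @return a validated nested configuration list.
#' @export
validate_config <- function(config = NULL) {
  if (is.character(config)) {
    if (!file.exists(config)) stopf("config file not found: %s", config)
    if (!requireNamespace("yaml", quietly = TRUE))
      stopf("the 'yaml' package is required to read YAML configs")
    config <- yaml::read_yaml(config)
    if (is.null(config)) config <- list()
  }
  cfg <- merge_config(pipeline_defaults(), config)
  with(cfg$preprocess, {
    if (snr_min_linear < 0) stopf("snr_min_linear must be >= 0")
    if (decimation < 1) stopf("decimation must be >= 1")
  })
  if (cfg$framework$B < 1) stopf("B must be >= 1")
  if (cfg$synthesis$snr_mean_db <= 0) stopf("snr_mean_db must be > 0")
  cfg
}

## Materialize the module config objects from a validated pipeline config.
build_configs <- function(cfg) {
  s <- cfg$synthesis
  list(
    synthesis = synthesis_config(
      class_counts = c("OSA" = s$n_osa, "non-OSA" = s$n_non_osa,
                       "excluded-gap" = s$n_gap),
      fs = s$fs, cycles_per_maneuver = s$cycles_per_maneuver,
      silent_duration = s$silent_duration,
      phase_duration_range = c(s$phase_duration_min, s$phase_duration_max),
      target_snr_db = c(mean = s$snr_mean_db, sd = s$snr_sd_db),
      signatures = default_signatures(s$signature_effect),
      band_jitter_db = s$band_jitter_db, jitter_cv = s$jitter_cv,
      null_anthro = isTRUE(s$null_anthro), seed = cfg$seed),
    preprocess = preprocess_config(
      snr_min_linear = cfg$preprocess$snr_min_linear,
      min_phases_per_maneuver = cfg$preprocess$min_phases_per_maneuver,
      envelope_window_ms = cfg$preprocess$envelope_window_ms,
      envelope_overlap = cfg$preprocess$envelope_overlap,
      antialias_band_hz = c(cfg$preprocess$antialias_low_hz,
                            cfg$preprocess$antialias_high_hz),
      antialias_order = cfg$preprocess$antialias_order,
      clean_band_hz = c(cfg$preprocess$clean_low_hz,
                        cfg$preprocess$clean_high_hz),
      clean_order = cfg$preprocess$clean_order,
      decimation = cfg$preprocess$decimation,
      ma_window_samples = cfg$preprocess$ma_window_samples,
      min_phase_s = cfg$preprocess$min_phase_s),
    wpd = wpd_config(levels = cfg$wpd$levels,
                     n_bands_kept = cfg$wpd$n_bands_kept,
                     tsallis_q = cfg$wpd$tsallis_q,
                     renyi_alpha = cfg$wpd$renyi_alpha),
    framework = framework_config(
      B = cfg$framework$B, k_features = cfg$framework$k_features,
      min_score = cfg$framework$min_score, outer_k = cfg$framework$outer_k,
      inner_repeats = cfg$framework$inner_repeats,
      threshold = cfg$framework$threshold, mode = cfg$framework$mode)
  )
}

#' Run the pipeline with per-stage caching
#'
#' Stages: `cohort` (metadata CSV), `features` (feature matrix CSV,
#' streamed synthesis + preprocessing + extraction), `evaluate` (metric
#' tables and report JSON). Cached stage outputs under `out_dir` are
#' reused unless `from` forces recomputation from a given stage onward.
#'
#' @param config pipeline configuration (path, list or `NULL`; see
#'   [validate_config()]).
#' @param out_dir output directory.
#' @param from first stage to recompute (`"cohort"`, `"features"`,
#'   `"evaluate"`), or `NULL` to reuse everything cached.
#' @param verbose progress messages.
#' @return run manifest (list), invisibly.
#' @export
run_pipeline <- function(config = NULL, out_dir = "osascreen-run",
                         from = NULL, verbose = TRUE) {
  cfg <- validate_config(config)
  configs <- build_configs(cfg)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- c("cohort", "features", "evaluate")
  if (!is.null(from)) from <- match.arg(from, stages)
  hash <- object_hash(cfg)
  manifest_path <- file.path(out_dir, "run_manifest.json")
  manifest <- list(config_hash = hash, seed = cfg$seed, stages = list())
  redo <- FALSE
  timing <- c()

  cohort_path <- file.path(out_dir, "cohort.csv")
  features_path <- file.path(out_dir, "features.csv")
  meta_path <- file.path(out_dir, "gated_meta.csv")
  report_path <- file.path(out_dir, "report.json")

  cached_ok <- function(path) file.exists(path) && !redo
  if (!is.null(from)) redo_from <- match(from, stages) else redo_from <- Inf
  ## stale caches (config changed) always recompute
  if (file.exists(manifest_path)) {
    old <- tryCatch(jsonlite::read_json(manifest_path), error = function(e) NULL)
    if (is.null(old) || !identical(old$config_hash, hash)) redo_from <- 1
  } else redo_from <- 1

  t0 <- Sys.time()
  if (!cached_ok(cohort_path) || redo_from <= 1) {
    redo <- TRUE
    if (verbose) message("[cohort] generating ", sum(cfg$synthesis$n_osa,
                         cfg$synthesis$n_non_osa, cfg$synthesis$n_gap),
                         " subjects")
    cohort <- generate_cohort(configs$synthesis)
    utils::write.csv(cohort, cohort_path, row.names = FALSE)
  } else cohort <- utils::read.csv(cohort_path, stringsAsFactors = FALSE)
  timing["cohort"] <- as.numeric(Sys.time() - t0, units = "secs")

  t0 <- Sys.time()
  if (!cached_ok(features_path) || redo_from <= 2) {
    redo <- TRUE
    if (verbose) message("[features] synthesizing and extracting")
    ex <- extract_cohort_features(cohort, syn_config = configs$synthesis,
                                  pre_config = configs$preprocess,
                                  wpd_cfg = configs$wpd, verbose = FALSE)
    fm <- as.data.frame(ex$features)
    names(fm) <- paste0("f", seq_len(640))
    utils::write.csv(cbind(subject_id = cohort$subject_id, fm),
                     features_path, row.names = FALSE)
    utils::write.csv(ex$meta, meta_path, row.names = FALSE)
    if (!is.null(ex$phase_log))
      utils::write.csv(ex$phase_log, file.path(out_dir, "phases.csv"),
                       row.names = FALSE)
  } else {
    fm <- utils::read.csv(features_path, stringsAsFactors = FALSE)
    ex <- list(features = as.matrix(fm[, -1]),
               meta = utils::read.csv(meta_path, stringsAsFactors = FALSE))
  }
  timing["features"] <- as.numeric(Sys.time() - t0, units = "secs")

  t0 <- Sys.time()
  if (!cached_ok(report_path) || redo_from <= 3) {
    if (verbose) message("[evaluate] cross-validated evaluation")
    keep <- !ex$meta$excluded
    X <- ex$features[keep, , drop = FALSE]
    meta <- ex$meta[keep, , drop = FALSE]
    evaluation <- evaluate_framework(X, meta, configs$framework,
                                     seed = cfg$seed)
    utils::write.csv(evaluation$per_fold,
                     file.path(out_dir, "per_fold.csv"), row.names = FALSE)
    utils::write.csv(evaluation$threshold_sweep,
                     file.path(out_dir, "threshold_sweep.csv"), row.names = FALSE)
    if (!is.null(evaluation$loso))
      utils::write.csv(evaluation$loso, file.path(out_dir, "loso.csv"),
                       row.names = FALSE)
    report <- list(
      pooled_confusion = evaluation$pooled_confusion,
      pooled_metrics = evaluation$pooled_metrics,
      pooled_auc = evaluation$pooled_auc,
      majority_metrics = evaluation$majority_metrics,
      gap = evaluation$gap,
      subjects_excluded = sum(ex$meta$excluded))
    jsonlite::write_json(report, report_path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  timing["evaluate"] <- as.numeric(Sys.time() - t0, units = "secs")

  manifest$stages <- as.list(timing)
  manifest$artifacts <- list(cohort = cohort_path, features = features_path,
                             report = report_path)
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(manifest)
}
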