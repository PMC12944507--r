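## ---------------------------------------------------------------------------
## Synthetic cohort: subject metadata with the anthropometric structure the
## screening pipeline assumes (class-dependent anthropometrics, AHI-defined
## labels, subgroup marginals), plus the synthesis configuration object.
## ---------------------------------------------------------------------------

LABEL_OSA <- "OSA"
LABEL_NON <- "non-OSA"
LABEL_GAP <- "excluded-gap"

#' Describe a planted spectral signature
#'
#' A signature shifts the log-energy of one analysis sub-band for all
#' breathing phases of matching subjects, creating a controllable acoustic
#' class/subgroup difference that the feature-selection and classification
#' stages can be tested against.
#'
#' @param band sub-band index, 1..10, on the decimated analysis grid
#'   (band `b` covers `[(b-1), b) * fs / 256` Hz for recording rate `fs`).
#' @param effect effect size in units of the per-subject band-gain standard
#'   deviation (`band_jitter_db`); positive boosts the band.
#' @param label `"OSA"`, `"non-OSA"` or `NULL` (all subjects).
#'   Intermediate-AHI ("excluded-gap") subjects receive half the effect of
#'   any class-targeted signature, emulating a phenotype between classes.
#' @param subgroup an anthropometric subgroup id (see [subgroup_ids()]) or
#'   `NULL` for no subgroup restriction.
#' @param maneuver `"MI"`, `"ME"`, `"NI"`, `"NE"` or `NULL` (all maneuvers).
#' @return a `spectral_signature` list.
#' @export
spectral_signature <- function(band, effect, label = LABEL_OSA,
                               subgroup = NULL, maneuver = NULL) {
  stopifnot(band %in% 1:10, is.finite(effect))
  if (!is.null(label)) stopifnot(label %in% c(LABEL_OSA, LABEL_NON))
  if (!is.null(subgroup)) stopifnot(subgroup %in% subgroup_ids())
  if (!is.null(maneuver)) stopifnot(maneuver %in% c("MI", "ME", "NI", "NE"))
  structure(list(band = as.integer(band), effect = effect, label = label,
                 subgroup = subgroup, maneuver = maneuver),
            class = "spectral_signature")
}

#' Default planted signature set
#'
#' A class-wide OSA shift in low-mid bands plus one subgroup-specific
#' marker per anthropometric stratum, loosely mirroring the kind of
#' subgroup-specific discriminative bands the screening framework is meant
#' to recover. Effect magnitudes are free parameters of the generator
#' (breathing-sound spectra of the two classes overlap heavily in reality).
#'
#' @param effect common effect size in within-class sd units (default 1).
#' @return list of [spectral_signature()] objects.
#' @export
default_signatures <- function(effect = 1.0) {
  if (effect == 0) return(list())
  list(
    spectral_signature(2, effect, LABEL_OSA, maneuver = "MI"),
    spectral_signature(3, effect, LABEL_OSA, maneuver = "ME"),
    spectral_signature(3, effect, LABEL_OSA, maneuver = "NI"),
    spectral_signature(5, effect, LABEL_OSA, maneuver = "NE"),
    spectral_signature(1, effect, LABEL_OSA, "male", "MI"),
    spectral_signature(6, effect, LABEL_OSA, "female", "NI"),
    spectral_signature(9, effect, LABEL_OSA, "high_age", "NE"),
    spectral_signature(4, effect, LABEL_OSA, "low_age", "NE"),
    spectral_signature(3, effect, LABEL_OSA, "high_bmi", "NI"),
    spectral_signature(8, effect, LABEL_OSA, "low_bmi", "MI"),
    spectral_signature(10, effect, LABEL_OSA, "high_mps", "NE"),
    spectral_signature(7, effect, LABEL_OSA, "low_mps", "NE"),
    spectral_signature(7, effect, LABEL_OSA, "non_current_smokers", "NE")
  )
}

#' Synthesis configuration
#'
#' Defaults reproduce the study conditions of the recording protocol:
#' 44.1 kHz mono recordings, one per subject per breathing route, a leading
#' breath-hold (silent period), five deep breathing cycles per route, and a
#' phase signal-to-noise ratio scattered around 10.7 +/- 4.2 dB. Cohort
#' class counts default to 149 OSA / 47 non-OSA / 32 intermediate-AHI.
#'
#' @param class_counts named counts for `"OSA"`, `"non-OSA"`,
#'   `"excluded-gap"`.
#' @param fs sampling rate, Hz.
#' @param cycles_per_maneuver breathing cycles per route.
#' @param silent_duration leading breath-hold, seconds.
#' @param phase_duration_range uniform range of phase durations, seconds.
#' @param inter_phase_pause pause between phases, seconds.
#' @param target_snr_db mean and sd of the per-phase SNR distribution
#'   across the dataset, dB. The sd is decomposed into a between-subject
#'   component and the within-recording component
#'   `snr_within_sd_db`, reflecting that recording-level factors
#'   (microphone fit, breathing effort) dominate the SNR spread.
#' @param snr_within_sd_db within-recording per-phase SNR scatter, dB.
#' @param signatures list of [spectral_signature()]; default
#'   `default_signatures(1)`.
#' @param band_jitter_db per-subject, per-band log-gain sd (dB); the unit
#'   in which signature effects are expressed.
#' @param jitter_cv per-phase coefficient of variation on duration and
#'   band gains.
#' @param noise_power variance of the stationary background noise floor.
#' @param null_anthro if `TRUE`, anthropometric distributions are pooled
#'   across classes (no anthropometric class signal); used for null
#'   experiments.
#' @param seed integer seed; all generator randomness derives from it.
#' @return a `synthesis_config` list.
#' @export
synthesis_config <- function(class_counts = c("OSA" = 149, "non-OSA" = 47,
                                              "excluded-gap" = 32),
                             fs = 44100,
                             cycles_per_maneuver = 5L,
                             silent_duration = 3,
                             phase_duration_range = c(1.2, 2.0),
                             inter_phase_pause = 0.45,
                             target_snr_db = c(mean = 10.7, sd = 4.2),
                             snr_within_sd_db = 1.5,
                             signatures = default_signatures(1.0),
                             band_jitter_db = 2.0,
                             jitter_cv = 0.10,
                             noise_power = 1e-4,
                             null_anthro = FALSE,
                             seed = 1L) {
  cfg <- list(class_counts = class_counts, fs = fs,
              cycles_per_maneuver = as.integer(cycles_per_maneuver),
              silent_duration = silent_duration,
              phase_duration_range = phase_duration_range,
              inter_phase_pause = inter_phase_pause,
              target_snr_db = target_snr_db,
              snr_within_sd_db = snr_within_sd_db, signatures = signatures,
              band_jitter_db = band_jitter_db, jitter_cv = jitter_cv,
              noise_power = noise_power, null_anthro = null_anthro,
              seed = as.integer(seed))
  validate_synthesis_config(cfg)
  structure(cfg, class = "synthesis_config")
}

validate_synthesis_config <- function(cfg) {
  cc <- cfg$class_counts
  if (is.null(names(cc)) ||
      !all(names(cc) %in% c(LABEL_OSA, LABEL_NON, LABEL_GAP)))
    stopf("class_counts must be named with OSA / non-OSA / excluded-gap")
  if (any(cc < 0)) stopf("class counts must be non-negative")
  if (cfg$target_snr_db[["mean"]] <= 0) stopf("target SNR mean must be > 0 dB")
  if (cfg$fs <= 0) stopf("fs must be positive")
  ## highest band edge used by any signature must sit below Nyquist of the
  ## decimated analysis rate (fs/4), i.e. band 10 top = 10 * fs/256 < fs/8
  if (length(cfg$signatures) > 0) {
    bmax <- max(vapply(cfg$signatures, function(s) s$band, integer(1)))
    if (bmax * cfg$fs / 256 >= cfg$fs / 2)
      stopf("signature band %d exceeds Nyquist", bmax)
  }
  if (any(cfg$phase_duration_range <= 0) ||
      diff(cfg$phase_duration_range) < 0)
    stopf("invalid phase_duration_range")
  invisible(cfg)
}

## Class-conditional anthropometric parameters. Marginal stratum
## probabilities (male, age>50, BMI>35, MpS>2, smoking) follow the study
## cohort's subgroup distribution; continuous values are drawn from the
## class-conditional normals truncated to the drawn stratum side.
class_params <- function(null_anthro = FALSE) {
  osa <- list(
    p_male = 99 / 149, p_high_age = 64 / 149, p_high_bmi = 66 / 149,
    age = c(48.1, 12.0), bmi = c(35.9, 8.9),
    mps = c(32, 26, 38, 53) / 149,
    smoking = c(84, 37, 28) / 149,          # never, former, current
    neck = c(44.7, 4.9), p_snoring = 0.968,
    mandible = c(0.05, 0.90, 0.05),
    ahi = c(42.6, 26.7)
  )
  non <- list(
    p_male = 19 / 47, p_high_age = 18 / 47, p_high_bmi = 11 / 47,
    age = c(44.1, 13.0), bmi = c(31.9, 6.8),
    mps = c(10, 11, 17, 9) / 47,
    smoking = c(34, 6, 7) / 47,
    neck = c(38.3, 3.8), p_snoring = 0.857,
    mandible = c(0.05, 0.90, 0.05),
    ahi = c(5.7, 2.6)
  )
  if (null_anthro) {
    w <- 149 / 196
    pool <- Map(function(a, b) w * a + (1 - w) * b, osa, non)
    osa <- non <- pool
  }
  gap <- Map(function(a, b) (a + b) / 2, osa, non)
  setNames(list(osa, non, gap), c(LABEL_OSA, LABEL_NON, LABEL_GAP))
}

## Inverse-CDF truncated normal draw (deterministic given the RNG stream).
rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  pl <- pnorm(lower, mean, sd)
  pu <- pnorm(upper, mean, sd)
  qnorm(runif(n, pl, pu), mean, sd)
}

#' Generate a synthetic study cohort
#'
#' Draws one record per subject with sex, age, BMI, Mallampati score,
#' smoking history, neck circumference, snoring, receding mandible and AHI.
#' Labels follow the AHI rule: non-OSA below 10 events/h, OSA above 15,
#' intermediate 10-15 flagged `"excluded-gap"`. Deterministic for a fixed
#' config seed.
#'
#' @param config a [synthesis_config()].
#' @return a `data.frame`, one row per subject.
#' @export
generate_cohort <- function(config) {
  validate_synthesis_config(config)
  set.seed(derive_seed(config$seed, "cohort"))
  params <- class_params(config$null_anthro)
  labels <- c(LABEL_OSA, LABEL_NON, LABEL_GAP)
  out <- list()
  for (lab in labels) {
    n <- unname(config$class_counts[lab])
    if (is.na(n)) n <- 0L
    if (n == 0L) next
    p <- params[[lab]]
    male <- runif(n) < p$p_male
    high_age <- runif(n) < p$p_high_age
    age <- round(ifelse(high_age,
                        rtruncnorm(n, p$age[1], p$age[2], 50 + 1e-9, 70),
                        rtruncnorm(n, p$age[1], p$age[2], 18, 50)))
    age <- pmin(pmax(age, 18), 70)
    high_bmi <- runif(n) < p$p_high_bmi
    bmi <- ifelse(high_bmi,
                  rtruncnorm(n, p$bmi[1], p$bmi[2], 35 + 1e-9, 65),
                  rtruncnorm(n, p$bmi[1], p$bmi[2], 17, 35))
    mps <- sample.int(4L, n, replace = TRUE, prob = p$mps)
    smoking <- c("never", "former", "current")[
      sample.int(3L, n, replace = TRUE, prob = p$smoking)]
    neck <- rtruncnorm(n, p$neck[1], p$neck[2], 28, 60)
    snoring <- runif(n) < p$p_snoring
    mandible <- sample(0:2, n, replace = TRUE, prob = p$mandible)
    ahi <- switch(lab,
      "OSA" = rtruncnorm(n, p$ahi[1], p$ahi[2], 15 + 1e-6, 130),
      "non-OSA" = rtruncnorm(n, p$ahi[1], p$ahi[2], 0, 10 - 1e-6),
      "excluded-gap" = runif(n, 10, 15))
    out[[lab]] <- data.frame(
      subject_id = character(n), sex = ifelse(male, "male", "female"),
      age = as.integer(age), bmi = round(bmi, 1), mps = mps,
      smoking = smoking, neck_circumference = round(neck, 1),
      snoring = snoring, receding_mandible = mandible,
      ahi = round(ahi, 1), label = lab, stringsAsFactors = FALSE)
  }
  cohort <- do.call(rbind, out)
  if (is.null(cohort))
    return(data.frame(subject_id = character(0), sex = character(0),
                      age = integer(0), bmi = numeric(0), mps = integer(0),
                      smoking = character(0), neck_circumference = numeric(0),
                      snoring = logical(0), receding_mandible = integer(0),
                      ahi = numeric(0), label = character(0)))
  rownames(cohort) <- NULL
  cohort$subject_id <- sprintf("S%04d", seq_len(nrow(cohort)))
  cohort
}

#' Apply the AHI-gap exclusion rule
#'
#' Removes intermediate-severity subjects (10 <= AHI <= 15) from a cohort,
#' leaving the binary OSA / non-OSA training population.
#'
#' @param cohort data.frame from [generate_cohort()].
#' @return the retained rows.
#' @export
apply_ahi_gap <- function(cohort) {
  cohort[cohort$ahi < 10 | cohort$ahi > 15, , drop = FALSE]
}
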