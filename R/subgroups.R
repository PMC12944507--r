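## ---------------------------------------------------------------------------
## Anthropometric sub-classifier strata. Four exhaustive complementary pairs
## (sex, age, BMI, Mallampati score) plus the non-current-smoker stratum:
## nine subgroups in total, each backing one sub-classifier.
## ---------------------------------------------------------------------------

#' Subgroup identifiers
#'
#' @return character vector of the nine anthropometric subgroup ids.
#' @export
subgroup_ids <- function() {
  c("male", "female", "high_age", "low_age", "high_bmi", "low_bmi",
    "high_mps", "low_mps", "non_current_smokers")
}

subgroup_predicates <- function() {
  list(
    male = function(s) s$sex == "male",
    female = function(s) s$sex == "female",
    high_age = function(s) s$age > 50,
    low_age = function(s) s$age <= 50,
    high_bmi = function(s) s$bmi > 35,
    low_bmi = function(s) s$bmi <= 35,
    high_mps = function(s) s$mps > 2,
    low_mps = function(s) s$mps <= 2,
    non_current_smokers = function(s) s$smoking %in% c("never", "former")
  )
}

#' Assign a subject to its relevant subgroups (the set Kx)
#'
#' Every subject matches exactly one of each complementary pair (sex,
#' age > 50, BMI > 35, MpS > 2; boundary values fall to the "low" side)
#' and additionally the non-current-smoker stratum unless a current
#' smoker, so |Kx| is 5 or 4.
#'
#' @param subject one cohort row (data.frame or list) with fields `sex`,
#'   `age`, `bmi`, `mps`, `smoking`.
#' @return character vector of subgroup ids.
#' @export
assign_subgroups <- function(subject) {
  req <- c("sex", "age", "bmi", "mps", "smoking")
  miss <- req[!req %in% names(subject)]
  if (length(miss) || anyNA(unlist(subject[req])))
    stopf("missing anthropometric field(s): %s",
          paste(c(miss, req[is.na(unlist(subject[req]))]), collapse = ", "))
  preds <- subgroup_predicates()
  ids <- names(preds)[vapply(preds, function(p) isTRUE(p(subject)), logical(1))]
  ids
}

#' Subgroup membership matrix for a cohort
#'
#' @param cohort cohort data.frame.
#' @return logical matrix, subjects x 9 subgroups.
#' @export
subgroup_membership <- function(cohort) {
  m <- cbind(
    male = cohort$sex == "male",
    female = cohort$sex == "female",
    high_age = cohort$age > 50,
    low_age = cohort$age <= 50,
    high_bmi = cohort$bmi > 35,
    low_bmi = cohort$bmi <= 35,
    high_mps = cohort$mps > 2,
    low_mps = cohort$mps <= 2,
    non_current_smokers = cohort$smoking %in% c("never", "former")
  )
  rownames(m) <- cohort$subject_id
  m
}
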