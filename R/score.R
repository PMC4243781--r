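#' Compute the Diabetes Remission Score
#'
#' Scores each patient on the seven preoperative components of the Diabetes
#' Remission Score (DRS). Each component contributes 1 point in its
#' favourable state and 2 points otherwise, so the total spans 7 (best
#' remission prospects) to 14 (worst):
#'
#' | component                | 1 point         | 2 points       |
#' |--------------------------|-----------------|----------------|
#' | age (years)              | 30 to 60        | < 30 or > 60   |
#' | BMI (kg/m^2)             | >= 27           | < 27           |
#' | duration of T2DM (years) | < 10            | >= 10          |
#' | microvascular disease    | absent          | present        |
#' | macrovascular disease    | absent          | present        |
#' | preoperative insulin use | no              | yes            |
#' | stimulated C-peptide     | >= 4 ng/mL      | < 4 ng/mL      |
#'
#' The age window is inclusive at both ends (30 and 60 score 1), thresholds
#' are applied to the raw value with no rounding, and a missing or
#' non-finite scoring field is a hard error -- never an imputation.
#'
#' The vascular-complication flags are taken as pre-adjudicated booleans.
#' Conventionally, microvascular means diabetic retinopathy, nephropathy or
#' neuropathy, and macrovascular means coronary, cerebrovascular or
#' peripheral arterial disease; the package documents but does not enforce
#' these definitions.
#'
#' @param patients Data frame with columns `age`, `bmi`, `dm_duration`,
#'   `microvascular`, `macrovascular`, `insulin_use`, `c_peptide_stim`.
#'   Flags accept logicals or `0/1`, `true/false`, `yes/no` (any case).
#'   Other columns are carried through untouched.
#' @return The input as a tibble with seven `score_*` columns (each 1 or 2),
#'   `drs_total` (integer, 7-14) and `drs_grade` (factor: `grade1` mild 7-8,
#'   `grade2` moderate 9-11, `grade3` severe 12-14).
#' @examples
#' patients <- tibble::tibble(
#'   age = c(45, 72), bmi = c(30, 22), dm_duration = c(5, 12),
#'   microvascular = c(FALSE, TRUE), macrovascular = c(FALSE, TRUE),
#'   insulin_use = c(FALSE, TRUE), c_peptide_stim = c(5, 2)
#' )
#' drs_score(patients)
#' @seealso [drs_predict()] to attach remission probabilities,
#'   [drs_eligibility()] for the study inclusion rules.
#' @export
drs_score <- function(patients) {
  checked <- validate_scoring_fields(patients)
  out <- tibble::as_tibble(patients)
  out$score_age <- ifelse(checked$age >= 30 & checked$age <= 60, 1L, 2L)
  out$score_bmi <- ifelse(checked$bmi >= 27, 1L, 2L)
  out$score_duration <- ifelse(checked$dm_duration < 10, 1L, 2L)
  out$score_micro <- ifelse(checked$microvascular, 2L, 1L)
  out$score_macro <- ifelse(checked$macrovascular, 2L, 1L)
  out$score_insulin <- ifelse(checked$insulin_use, 2L, 1L)
  out$score_cpeptide <- ifelse(checked$c_peptide_stim >= 4, 1L, 2L)
  out$drs_total <- out$score_age + out$score_bmi + out$score_duration +
    out$score_micro + out$score_macro + out$score_insulin + out$score_cpeptide
  out$drs_grade <- drs_grade(out$drs_total)
  out
}

#' Severity grade of a DRS total
#'
#' Maps total scores to the three severity grades: grade 1 (mild, DRS 7-8),
#' grade 2 (moderate, 9-11) and grade 3 (severe, 12-14).
#'
#' @param drs_total Integer vector of total scores in 7-14.
#' @return Factor with levels `grade1`, `grade2`, `grade3`.
#' @examples
#' drs_grade(c(7, 9, 13))
#' @export
drs_grade <- function(drs_total) {
  check_drs_total(drs_total)
  cut(drs_total, breaks = c(6.5, 8.5, 11.5, 14.5),
      labels = c("grade1", "grade2", "grade3"))
}

check_drs_total <- function(drs_total, call = rlang::caller_env()) {
  if (!is.numeric(drs_total) || any(!is.finite(drs_total)) ||
      any(drs_total < 7 | drs_total > 14) || any(drs_total != round(drs_total))) {
    abort("`drs_total` must contain integers between 7 and 14.", call = call)
  }
  invisible(drs_total)
}
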