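#' Study eligibility check per procedure
#'
#' Applies the trial's inclusion criteria to each patient for the requested
#' procedure and records every violated criterion:
#'
#' * `age_window` -- age between 25 and 70 years (inclusive);
#' * `duration_minimum` -- T2DM duration > 1 year (IISG) or > 5 years (IIDSG);
#' * `hba1c_above_7` -- poor glycaemic control, HbA1c > 7%;
#' * `bmi_minimum` -- BMI >= 20 kg/m^2 (IISG) or > 18.5 kg/m^2 (IIDSG);
#' * `c_peptide_minimum` -- stimulated C-peptide > 1.5 ng/mL (strict).
#'
#' Exclusion diagnoses are never adjudicated from raw data; when the optional
#' boolean columns `type1_diabetes`, `undetectable_fasting_c_peptide`,
#' `recent_ketoacidosis`, `pregnancy` or `severe_comorbidity` are present and
#' `TRUE`, the matching criterion id is added. `stable_weight` (an inclusion
#' criterion with no operational definition) is likewise accepted only as an
#' optional flag: when present and `FALSE` the criterion `stable_weight` fails.
#'
#' @param patients Data frame with the scoring columns plus `hba1c`
#'   (required for this check) and any optional exclusion flags.
#' @param procedure `"IISG"` or `"IIDSG"`.
#' @return The input as a tibble plus `eligible` (logical) and
#'   `failed_criteria` (list-column of character ids, empty when eligible).
#' @examples
#' p <- tibble::tibble(
#'   age = 24, bmi = 25, dm_duration = 4, microvascular = FALSE,
#'   macrovascular = FALSE, insulin_use = TRUE, c_peptide_stim = 3, hba1c = 8.2
#' )
#' drs_eligibility(p, "IISG")$failed_criteria
#' @export
drs_eligibility <- function(patients, procedure) {
  check_procedure(procedure)
  checked <- validate_scoring_fields(patients)
  if (!"hba1c" %in% names(checked)) {
    abort("Column `hba1c` is required for the eligibility check.")
  }
  if (any(!is.finite(checked$hba1c))) {
    abort("Column `hba1c` is missing or non-finite for some rows.")
  }

  dur_min <- if (procedure == "IISG") 1 else 5
  fails <- list(
    age_window = checked$age < 25 | checked$age > 70,
    duration_minimum = checked$dm_duration <= dur_min,
    hba1c_above_7 = checked$hba1c <= 7,
    bmi_minimum = if (procedure == "IISG") checked$bmi < 20 else checked$bmi <= 18.5,
    c_peptide_minimum = checked$c_peptide_stim <= 1.5
  )

  exclusion_flags <- c(
    "type1_diabetes", "undetectable_fasting_c_peptide",
    "recent_ketoacidosis", "pregnancy", "severe_comorbidity"
  )
  for (flag in intersect(exclusion_flags, names(checked))) {
    v <- parse_flag(checked[[flag]], flag)
    fails[[flag]] <- !is.na(v) & v
  }
  if ("stable_weight" %in% names(checked)) {
    v <- parse_flag(checked$stable_weight, "stable_weight")
    fails$stable_weight <- !is.na(v) & !v
  }

  fail_mat <- do.call(cbind, fails)
  out <- tibble::as_tibble(patients)
  out$failed_criteria <- apply(fail_mat, 1, function(row) names(fails)[row],
                               simplify = FALSE)
  out$eligible <- lengths(out$failed_criteria) == 0L
  out
}

#' Classify diabetes remission
#'
#' The study endpoint: remission is HbA1c below 6.5% without requiring any
#' medication for diabetes control (comparable to ADA partial remission).
#' The HbA1c inequality is strict: 6.5% exactly is not remission.
#'
#' @param hba1c Numeric vector, glycated haemoglobin in percent (finite, > 0).
#' @param on_diabetes_medication Logical vector (recycled if length 1):
#'   is the patient still taking any glucose-lowering medication?
#' @return Logical vector, `TRUE` when in remission.
#' @examples
#' drs_remission(c(6.4, 6.4, 6.5), c(FALSE, TRUE, FALSE))
#' @export
drs_remission <- function(hba1c, on_diabetes_medication) {
  if (!is.numeric(hba1c) || any(!is.finite(hba1c)) || any(hba1c <= 0)) {
    abort("`hba1c` must be finite and positive.")
  }
  med <- parse_flag(on_diabetes_medication, "on_diabetes_medication")
  if (any(is.na(med))) abort("`on_diabetes_medication` must not be missing.")
  hba1c < 6.5 & !med
}
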