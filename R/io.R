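#' Read a patient table from CSV
#'
#' Reads and validates a per-patient CSV with the scoring columns
#' `patient_id, age, bmi, dm_duration, microvascular, macrovascular,
#' insulin_use, c_peptide_stim` and the optional columns `hba1c`,
#' `procedure` (IISG or IIDSG), `on_medication`, `remission` and any
#' exclusion flags. Boolean columns accept `0/1`, `true/false`, `yes/no` in
#' any case. A malformed row fails loudly with its row number and field;
#' nothing is imputed.
#'
#' @param path Path to a CSV file with a header row.
#' @return A validated tibble.
#' @examples
#' csv <- system.file("extdata", "example_patients.csv", package = "drscore")
#' read_patients(csv)
#' @export
read_patients <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  raw <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  if (nrow(raw) == 0) abort(sprintf("Input file %s has no data rows.", path))

  numeric_cols <- intersect(c(drs_numeric_fields, "hba1c", "hba1c_followup"), names(raw))
  flag_cols <- intersect(
    c(drs_flag_fields, "on_medication", "remission", "on_medication_followup",
      "type1_diabetes", "undetectable_fasting_c_peptide", "recent_ketoacidosis",
      "pregnancy", "severe_comorbidity", "stable_weight"),
    names(raw)
  )
  out <- raw
  for (col in numeric_cols) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(!is.na(raw[[col]]) & is.na(v))
    if (length(bad)) {
      abort(sprintf("Row %s: column `%s` is not numeric (value %s).",
                    bad[1], col, raw[[col]][bad[1]]))
    }
    out[[col]] <- v
  }
  for (col in flag_cols) {
    parsed <- tryCatch(parse_flag(raw[[col]], col), error = function(e) e)
    if (inherits(parsed, "error")) {
      key <- tolower(trimws(raw[[col]]))
      bad <- which(!is.na(raw[[col]]) &
                     !key %in% c("0", "1", "true", "false", "yes", "no", "y", "n", ""))
      abort(sprintf("Row %s: column `%s` is not a recognised boolean (value %s).",
                    bad[1], col, raw[[col]][bad[1]]))
    }
    out[[col]] <- parsed
  }
  if ("procedure" %in% names(out)) {
    bad <- which(!is.na(out$procedure) & !out$procedure %in% procedures)
    if (length(bad)) {
      abort(sprintf("Row %s: column `procedure` must be IISG or IIDSG (value %s).",
                    bad[1], out$procedure[bad[1]]))
    }
  }
  validate_scoring_fields(out)
}
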