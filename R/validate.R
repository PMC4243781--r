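# Internal validation helpers shared by the scoring and eligibility verbs.

# Seven fields required to compute a DRS.
drs_fields <- c(
  "age", "bmi", "dm_duration",
  "microvascular", "macrovascular", "insulin_use",
  "c_peptide_stim"
)

drs_numeric_fields <- c("age", "bmi", "dm_duration", "c_peptide_stim")
drs_flag_fields <- c("microvascular", "macrovascular", "insulin_use")

procedures <- c("IISG", "IIDSG")

check_procedure <- function(procedure, arg = "procedure") {
  if (length(procedure) != 1L || !procedure %in% procedures) {
    abort(sprintf(
      "`%s` must be one of %s, not %s.",
      arg, paste0('"', procedures, '"', collapse = ", "),
      paste0('"', as.character(procedure), '"', collapse = ", ")
    ))
  }
  procedure
}

# Accept 0/1, true/false, yes/no (any case) and native logicals.
parse_flag <- function(x, field) {
  if (is.logical(x)) return(x)
  if (is.numeric(x)) {
    bad <- !is.na(x) & !x %in% c(0, 1)
    if (any(bad)) {
      abort(sprintf("Column `%s` has non-boolean numeric values: %s.",
                    field, paste(unique(x[bad]), collapse = ", ")))
    }
    return(x == 1)
  }
  key <- tolower(trimws(as.character(x)))
  out <- dplyr::case_when(
    key %in% c("1", "true", "yes", "y") ~ TRUE,
    key %in% c("0", "false", "no", "n") ~ FALSE,
    is.na(x) | key == "" ~ NA,
    .default = NA
  )
  unmapped <- !is.na(x) & key != "" & is.na(out)
  if (any(unmapped)) {
    abort(sprintf("Column `%s` has unrecognised boolean values: %s.",
                  field, paste(unique(x[unmapped]), collapse = ", ")))
  }
  out
}

# Hard-error policy: a missing or non-finite scoring field is never imputed,
# because a one-point slip in a 7-14 score changes the grade.
validate_scoring_fields <- function(patients, call = rlang::caller_env()) {
  stopifnot(is.data.frame(patients))
  missing_cols <- setdiff(drs_fields, names(patients))
  if (length(missing_cols)) {
    abort(sprintf("Missing required scoring column(s): %s.",
                  paste0("`", missing_cols, "`", collapse = ", ")), call = call)
  }
  patients <- dplyr::mutate(
    patients,
    dplyr::across(dplyr::all_of(drs_flag_fields), ~ parse_flag(.x, dplyr::cur_column()))
  )
  for (field in drs_numeric_fields) {
    v <- patients[[field]]
    if (!is.numeric(v)) {
      abort(sprintf("Column `%s` must be numeric.", field), call = call)
    }
    bad <- which(!is.finite(v))
    if (length(bad)) {
      abort(sprintf("Column `%s` is missing or non-finite for row(s) %s; the score is never imputed.",
                    field, paste(head(bad, 5), collapse = ", ")), call = call)
    }
    if (any(v < 0)) {
      abort(sprintf("Column `%s` must be non-negative.", field), call = call)
    }
  }
  if (any(patients$bmi <= 0)) {
    abort("Column `bmi` must be strictly positive.", call = call)
  }
  for (field in drs_flag_fields) {
    bad <- which(is.na(patients[[field]]))
    if (length(bad)) {
      abort(sprintf("Column `%s` is missing for row(s) %s; the score is never imputed.",
                    field, paste(head(bad, 5), collapse = ", ")), call = call)
    }
  }
  patients
}

#' Round half away from zero
#'
#' Base R's `round()` rounds half to even; published clinical tables almost
#' always round half up (45.65% prints as 46%). Used everywhere a percentage
#' is reported.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places to keep.
#' @return Numeric vector rounded half away from zero.
#' @examples
#' round_half_up(c(0.5, 1.5, 45.65), 0)
#' @export
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}
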