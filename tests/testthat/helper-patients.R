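# Build patient rows with all-favourable defaults; override any field.
make_patients <- function(..., n = NULL) {
  defaults <- list(
    age = 45, bmi = 30, dm_duration = 5,
    microvascular = FALSE, macrovascular = FALSE, insulin_use = FALSE,
    c_peptide_stim = 5, hba1c = 8.5
  )
  overrides <- list(...)
  fields <- utils::modifyList(defaults, overrides)
  if (is.null(n)) n <- max(c(1L, lengths(fields)))
  tibble::as_tibble(lapply(fields, rep_len, n))
}

# All 2^7 combinations of favourable/unfavourable component states.
all_component_combos <- function() {
  grid <- expand.grid(rep(list(c(FALSE, TRUE)), 7))
  names(grid) <- c("age", "bmi", "duration", "micro", "macro", "insulin", "cpep")
  make_patients(
    age = ifelse(grid$age, 75, 45),
    bmi = ifelse(grid$bmi, 22, 30),
    dm_duration = ifelse(grid$duration, 15, 5),
    microvascular = grid$micro,
    macrovascular = grid$macro,
    insulin_use = grid$insulin,
    c_peptide_stim = ifelse(grid$cpep, 2, 5),
    n = nrow(grid)
  )
}
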