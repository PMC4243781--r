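test_that("extreme profiles score the minimum and maximum totals", {
  best <- drs_score(make_patients())
  expect_equal(best$drs_total, 7L)
  expect_equal(as.character(best$drs_grade), "grade1")
  expect_true(all(unlist(best[paste0("score_", c("age", "bmi", "duration",
                                                 "micro", "macro", "insulin",
                                                 "cpeptide"))]) == 1L))

  worst <- drs_score(make_patients(
    age = 72, bmi = 22, dm_duration = 12,
    microvascular = TRUE, macrovascular = TRUE, insulin_use = TRUE,
    c_peptide_stim = 2
  ))
  expect_equal(worst$drs_total, 14L)
  expect_equal(as.character(worst$drs_grade), "grade3")
})

test_that("numeric cut-offs follow the published component table at, below and above each threshold", {
  # component table semantics: age 30-60 inclusive; BMI >= 27; duration >= 10
  # unfavourable; C-peptide >= 4 favourable
  cases <- tibble::tribble(
    ~field,            ~value, ~column,          ~expected,
    "age",              29.9,  "score_age",       2L,
    "age",              30,    "score_age",       1L,
    "age",              30.1,  "score_age",       1L,
    "age",              59.9,  "score_age",       1L,
    "age",              60,    "score_age",       1L,
    "age",              60.1,  "score_age",       2L,
    "bmi",              26.9,  "score_bmi",       2L,
    "bmi",              27,    "score_bmi",       1L,
    "bmi",              27.1,  "score_bmi",       1L,
    "dm_duration",      9.9,   "score_duration",  1L,
    "dm_duration",      10,    "score_duration",  2L,
    "dm_duration",      10.1,  "score_duration",  2L,
    "c_peptide_stim",   3.9,   "score_cpeptide",  2L,
    "c_peptide_stim",   4,     "score_cpeptide",  1L,
    "c_peptide_stim",   4.1,   "score_cpeptide",  1L
  )
  for (i in seq_len(nrow(cases))) {
    p <- make_patients()
    p[[cases$field[i]]] <- cases$value[i]
    scored <- drs_score(p)
    expect_equal(scored[[cases$column[i]]], cases$expected[i],
                 info = sprintf("%s = %s", cases$field[i], cases$value[i]))
  }
})

test_that("a mixed boundary profile combines component scores correctly", {
  p <- make_patients(age = 60, bmi = 27, dm_duration = 10, insulin_use = TRUE,
                     c_peptide_stim = 4)
  scored <- drs_score(p)
  expect_equal(scored$score_age, 1L)
  expect_equal(scored$score_bmi, 1L)
  expect_equal(scored$score_duration, 2L)
  expect_equal(scored$score_micro, 1L)
  expect_equal(scored$score_macro, 1L)
  expect_equal(scored$score_insulin, 2L)
  expect_equal(scored$score_cpeptide, 1L)
  expect_equal(scored$drs_total, 9L)
  expect_equal(as.character(scored$drs_grade), "grade2")
})

test_that("every component combination yields a total equal to 7 plus the unfavourable count", {
  combos <- all_component_combos()
  scored <- drs_score(combos)
  subscores <- as.matrix(scored[paste0("score_", c("age", "bmi", "duration",
                                                   "micro", "macro", "insulin",
                                                   "cpeptide"))])
  expect_true(all(subscores %in% 1:2))
  expect_equal(scored$drs_total, unname(rowSums(subscores)))
  expect_true(all(scored$drs_total >= 7 & scored$drs_total <= 14))
  expect_setequal(unique(scored$drs_total), 7:14)
  expect_equal(
    as.character(scored$drs_grade),
    dplyr::case_when(scored$drs_total <= 8 ~ "grade1",
                     scored$drs_total <= 11 ~ "grade2",
                     .default = "grade3")
  )
})

test_that("flipping a single component to unfavourable adds exactly one point", {
  base <- make_patients()
  flips <- list(
    age = list(age = 75), bmi = list(bmi = 22), duration = list(dm_duration = 15),
    micro = list(microvascular = TRUE), macro = list(macrovascular = TRUE),
    insulin = list(insulin_use = TRUE), cpep = list(c_peptide_stim = 2)
  )
  base_scored <- drs_score(base)
  sub_cols <- paste0("score_", c("age", "bmi", "duration", "micro", "macro",
                                 "insulin", "cpeptide"))
  for (nm in names(flips)) {
    flipped <- drs_score(do.call(make_patients, flips[[nm]]))
    expect_equal(flipped$drs_total, base_scored$drs_total + 1L, info = nm)
    changed <- vapply(sub_cols, function(cl) flipped[[cl]] != base_scored[[cl]],
                      logical(1))
    expect_equal(sum(changed), 1L, info = nm)
  }
})

test_that("random valid records always score within bounds (property)", {
  withr::with_seed(42, {
    n <- 500
    p <- tibble::tibble(
      age = runif(n, 18, 90), bmi = runif(n, 15, 50),
      dm_duration = runif(n, 0, 40),
      microvascular = sample(c(TRUE, FALSE), n, TRUE),
      macrovascular = sample(c(TRUE, FALSE), n, TRUE),
      insulin_use = sample(c(TRUE, FALSE), n, TRUE),
      c_peptide_stim = runif(n, 0, 12)
    )
    scored <- drs_score(p)
    expect_true(all(scored$drs_total >= 7 & scored$drs_total <= 14))
    expect_equal(scored$drs_total,
                 scored$score_age + scored$score_bmi + scored$score_duration +
                   scored$score_micro + scored$score_macro +
                   scored$score_insulin + scored$score_cpeptide)
  })
})

test_that("missing or invalid scoring fields fail loudly, naming the field", {
  expect_error(drs_score(make_patients(age = NA)), "`age`")
  expect_error(drs_score(make_patients(c_peptide_stim = Inf)), "`c_peptide_stim`")
  expect_error(drs_score(make_patients(microvascular = NA)), "`microvascular`")
  expect_error(drs_score(make_patients()[-1]), "`age`")
  expect_error(drs_score(make_patients(bmi = 0)), "`bmi`")
  expect_error(drs_score(make_patients(dm_duration = -1)), "`dm_duration`")
})

test_that("boolean flags are accepted in CSV-style spellings", {
  p <- make_patients()
  p$microvascular <- "Yes"; p$macrovascular <- "0"; p$insulin_use <- "FALSE"
  scored <- drs_score(p)
  expect_equal(scored$score_micro, 2L)
  expect_equal(scored$score_macro, 1L)
  expect_equal(scored$score_insulin, 1L)
})

test_that("drs_grade validates its input range", {
  expect_error(drs_grade(6), "between 7 and 14")
  expect_error(drs_grade(15), "between 7 and 14")
  expect_error(drs_grade(7.5), "between 7 and 14")
})
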