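#' Run the full scoring pipeline on a patient table
#'
#' Chains the package's verbs end to end: read/validate, score, (when
#' `hba1c` is present) eligibility, band predictions, and the
#' remitter/non-remitter analysis when an observed `remission` column
#' exists. Writes the scored cohort (`scored.csv`), predictions
#' (`predicted.csv`), eligibility verdicts (`eligibility.csv`, criteria
#' comma-joined), and a JSON analysis report with a provenance block
#' (package version, seed, config hash). Outputs are written atomically: on
#' any validation failure no partial files are left behind.
#'
#' @param input Path to a patient CSV (see [read_patients()]) or a data
#'   frame.
#' @param out_dir Output directory, created if needed.
#' @param procedure Optional procedure for the eligibility check; defaults
#'   to the per-patient `procedure` column when present.
#' @param seed Integer recorded in the provenance block (the pipeline itself
#'   is deterministic; the seed matters when the input was generated).
#' @param model A [drs_outcome_model()].
#' @param variant t-test variant for the comparison report.
#' @return Invisibly, a list of class `drs_bundle`: `scored`, `predicted`,
#'   `eligibility` (possibly `NULL`), `comparison` (possibly `NULL`),
#'   `report` (the JSON-ready list) and `paths` of the written files.
#' @examples
#' csv <- system.file("extdata", "example_patients.csv", package = "drscore")
#' bundle <- run_drs_pipeline(csv, out_dir = tempfile("drs-run-"))
#' names(bundle$paths)
#' @export
run_drs_pipeline <- function(input, out_dir, procedure = NULL, seed = 1L,
                             model = drs_outcome_model(),
                             variant = c("welch", "pooled")) {
  variant <- match.arg(variant)
  patients <- if (is.data.frame(input)) {
    validate_scoring_fields(input)
  } else {
    read_patients(input)
  }

  scored <- drs_score(patients)
  predicted <- drs_predict(scored, model)

  eligibility <- NULL
  if ("hba1c" %in% names(patients)) {
    eligibility <- if (!is.null(procedure)) {
      drs_eligibility(patients, procedure)
    } else if ("procedure" %in% names(patients) && !any(is.na(patients$procedure))) {
      patients |>
        dplyr::group_by(.data$procedure) |>
        dplyr::group_modify(~ drs_eligibility(.x, .y$procedure)) |>
        dplyr::ungroup()
    } else {
      NULL
    }
  }

  comparison <- NULL
  if ("remission" %in% names(scored) && !any(is.na(scored$remission))) {
    comparison <- compare_remission_groups(scored, variant = variant)
  }

  config <- list(
    procedure = procedure, variant = variant,
    model_bands = as.data.frame(model)
  )
  report <- list(
    provenance = list(
      package = "drscore",
      version = as.character(utils::packageVersion("drscore")),
      seed = as.integer(seed),
      config_hash = rlang::hash(config),
      n_patients = nrow(scored)
    ),
    score_summary = as.list(drs_summarize(scored$drs_total)),
    grade_counts = as.list(table(scored$drs_grade)),
    predictions = list(
      mean_remission_prob = mean(predicted$remission_prob),
      n_extrapolated = sum(predicted$extrapolated)
    ),
    eligibility = if (!is.null(eligibility)) {
      list(n_eligible = sum(eligibility$eligible),
           n_ineligible = sum(!eligibility$eligible))
    },
    comparison = if (!is.null(comparison)) {
      list(by_procedure = as.data.frame(comparison$by_procedure),
           summaries = as.data.frame(comparison$summaries),
           n_tests = comparison$n_tests)
    }
  )

  # stage everything, then move into place so failures leave no partial bundle
  stage <- tempfile("drs-stage-")
  dir.create(stage, recursive = TRUE)
  on.exit(unlink(stage, recursive = TRUE), add = TRUE)
  readr::write_csv(scored, file.path(stage, "scored.csv"))
  readr::write_csv(predicted, file.path(stage, "predicted.csv"))
  if (!is.null(eligibility)) {
    flat <- eligibility
    flat$failed_criteria <- purrr::map_chr(flat$failed_criteria, paste, collapse = ";")
    readr::write_csv(flat, file.path(stage, "eligibility.csv"))
  }
  jsonlite::write_json(report, file.path(stage, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  staged <- list.files(stage, full.names = TRUE)
  ok <- file.copy(staged, out_dir, overwrite = TRUE)
  if (!all(ok)) abort(sprintf("Could not write outputs to %s.", out_dir))

  paths <- setNames(file.path(out_dir, basename(staged)), basename(staged))
  invisible(structure(
    list(scored = scored, predicted = predicted, eligibility = eligibility,
         comparison = comparison, report = report, paths = paths),
    class = "drs_bundle"
  ))
}

#' Recompute the published aggregates from the package's own machinery
#'
#' A reproduction report: every in-scope printed aggregate is recomputed at
#' run time -- the between-group t-test from the printed summaries, the
#' within-group remitter vs non-remitter tests, band probabilities at the
#' partial scores, and the remission rates obtained by reconstructing
#' per-score cohorts from the printed aggregates and re-analysing them with
#' [compare_remission_groups()]. Printed values that cannot be recovered
#' from the publication (a cross-group p-value, an unsized subgroup test,
#' and the BMI-stratified DRS rows that duplicate the remission split) are
#' listed under `excluded` with reasons, and are never compared against.
#'
#' @param variant t-test variant for the recomputations.
#' @param subgroup_moments Use the full constraint sets (printed subgroup
#'   moments included) for the reconstructions? The default `FALSE` uses the
#'   core sets; the full sets admit no solution at the printed tolerances
#'   (see [drs_constraints_iisg()]), which the report then records as
#'   `feasible = FALSE` with no remission rate.
#' @return List of class `drs_reproduction` with elements `between_groups`,
#'   `within_groups`, `bands`, `remission_rates`, `excluded`.
#' @examples
#' rep <- drs_reproduce()
#' rep$remission_rates
#' @export
drs_reproduce <- function(variant = c("welch", "pooled"), subgroup_moments = FALSE) {
  variant <- match.arg(variant)
  agg <- published_aggregates()
  model <- drs_outcome_model()

  between <- drs_t_test(
    list(n = agg$IISG$n, mean = agg$IISG$mean, sd = agg$IISG$sd),
    list(n = agg$IIDSG$n, mean = agg$IIDSG$mean, sd = agg$IIDSG$sd),
    variant
  )

  within <- purrr::map(list(IISG = agg$IISG, IIDSG = agg$IIDSG), function(block) {
    n_rem <- block$remission_total
    drs_t_test(
      list(n = n_rem, mean = block$remitter$mean, sd = block$remitter$sd),
      list(n = block$n - n_rem, mean = block$nonremitter$mean, sd = block$nonremitter$sd),
      variant
    )
  })

  bands <- tibble::tibble(
    procedure = c("IISG", "IIDSG"),
    partial_score = c(agg$IISG$partial_score, agg$IIDSG$partial_score),
    computed_pct = c(
      100 * as.numeric(predict_remission(agg$IISG$partial_score, "IISG", model)),
      100 * as.numeric(predict_remission(agg$IIDSG$partial_score, "IIDSG", model))
    ),
    printed_pct = c(agg$IISG$partial_pct, agg$IIDSG$partial_pct)
  )

  rates <- purrr::map(
    list(IISG = drs_constraints_iisg(subgroup_moments),
         IIDSG = drs_constraints_iidsg(subgroup_moments)),
    function(cn) {
      rec <- reconstruct_score_distribution(cn)
      if (!nrow(rec$solutions)) {
        return(list(feasible = FALSE, n_solutions = 0L,
                    computed_rate_pct = NA_real_))
      }
      cmp <- compare_remission_groups(reconstruction_cohort(rec), variant = variant)
      list(feasible = TRUE, n_solutions = nrow(rec$solutions),
           computed_rate_pct = cmp$by_procedure$remission_rate_pct[1])
    }
  )
  remission_rates <- tibble::tibble(
    procedure = names(rates),
    feasible = unname(purrr::map_lgl(rates, "feasible")),
    n_solutions = unname(purrr::map_int(rates, "n_solutions")),
    computed_rate_pct = unname(purrr::map_dbl(rates, "computed_rate_pct")),
    printed_rate_pct = c(agg$IISG$remission_pct, agg$IIDSG$remission_pct)
  )

  excluded <- tibble::as_tibble(agg$irreproducible)
  excluded$reproducible <- FALSE

  structure(
    list(
      between_groups = list(
        computed_p = between$p_value, printed_p = agg$between_groups$p,
        variant = variant, test = between
      ),
      within_groups = purrr::map(within, function(tt) {
        list(computed_p = tt$p_value, printed = "p < 0.0001", variant = variant)
      }),
      bands = bands,
      remission_rates = remission_rates,
      excluded = excluded
    ),
    class = "drs_reproduction"
  )
}

#' @export
print.drs_reproduction <- function(x, ...) {
  cat("Reproduction of the published aggregates\n\n")
  cat(sprintf("Between groups (%s): computed p = %.4g, printed p = %.4g\n",
              x$between_groups$variant, x$between_groups$computed_p,
              x$between_groups$printed_p))
  for (proc in names(x$within_groups)) {
    cat(sprintf("%s remitters vs non-remitters: computed p = %.3g (%s)\n",
                proc, x$within_groups[[proc]]$computed_p,
                x$within_groups[[proc]]$printed))
  }
  cat("\nBand percentages at the partial scores:\n")
  print(x$bands)
  cat("\nRemission rates from reconstructed cohorts:\n")
  print(x$remission_rates)
  cat(sprintf("\n%d printed value(s) documented as irreproducible and excluded.\n",
              nrow(x$excluded)))
  invisible(x)
}
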