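# broom-style tidiers so results drop straight into dplyr/ggplot pipelines

#' Tidy a summary-statistics t-test
#'
#' @param x A `drs_ttest` from [drs_t_test()].
#' @param ... Unused.
#' @return One-row tibble with `estimate` (mean difference), `statistic`,
#'   `parameter` (df), `p.value` and `method`.
#' @export
tidy.drs_ttest <- function(x, ...) {
  tibble::tibble(
    estimate = x$mean_difference,
    statistic = x$t_statistic,
    parameter = x$degrees_of_freedom,
    p.value = x$p_value,
    method = sprintf("Two-sided unpaired t-test (%s)", x$variant)
  )
}

#' @rdname tidy.drs_ttest
#' @export
glance.drs_ttest <- function(x, ...) tidy(x, ...)

#' Tidy a remission-group comparison
#'
#' @param x A `drs_comparison` from [compare_remission_groups()].
#' @param ... Unused.
#' @return `tidy()`: the per-stratum/per-group summaries; `glance()`: one
#'   row per stratum with rates and test results.
#' @export
tidy.drs_comparison <- function(x, ...) x$summaries

#' @rdname tidy.drs_comparison
#' @export
glance.drs_comparison <- function(x, ...) x$by_procedure

#' Tidy a score-distribution reconstruction
#'
#' @param x A `drs_reconstruction` from [reconstruct_score_distribution()].
#' @param ... Unused.
#' @return `tidy()`: long tibble with `solution_id`, `drs_total`, `count`
#'   and `remitters` per score; `glance()`: one row with the label,
#'   feasibility and solution count.
#' @export
tidy.drs_reconstruction <- function(x, ...) {
  cn <- x$constraints
  purrr::map_dfr(seq_len(nrow(x$solutions)), function(i) {
    counts <- x$solutions$counts[[i]]
    scores <- as.integer(names(counts))
    remitters <- integer(length(scores))
    remitters[scores %in% cn$full_remission_scores] <-
      counts[scores %in% cn$full_remission_scores]
    if (!is.na(cn$partial_score)) {
      remitters[scores == cn$partial_score] <- x$solutions$partial_remitters[i]
    }
    tibble::tibble(
      solution_id = x$solutions$solution_id[i],
      drs_total = scores,
      count = as.integer(counts),
      remitters = remitters
    )
  })
}

#' @rdname tidy.drs_reconstruction
#' @export
glance.drs_reconstruction <- function(x, ...) {
  tibble::tibble(
    label = x$constraints$label,
    n = x$constraints$n,
    feasible = nrow(x$solutions) > 0,
    n_solutions = nrow(x$solutions)
  )
}
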