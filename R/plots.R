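# autoplot() methods for the package's result objects

#' Plot the remission band model
#'
#' Step plot of remission probability against the DRS total for both
#' procedures, with the extrapolated region (scores below the procedure's
#' observed range) drawn hollow.
#'
#' @param object A [drs_outcome_model()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.drs_outcome_model <- function(object, ...) {
  grid <- tidyr::expand_grid(drs_total = 7:14, procedure = procedures)
  grid$prob <- as.numeric(
    predict_remission(grid$drs_total, grid$procedure, object,
                      warn_extrapolation = FALSE)
  )
  ranges <- attr(object, "observed_range")
  grid$observed <- purrr::map2_lgl(grid$drs_total, grid$procedure, function(s, p) {
    s >= ranges[[p]][1] && s <= ranges[[p]][2]
  })
  ggplot2::ggplot(grid, ggplot2::aes(x = .data$drs_total, y = .data$prob,
                                     colour = .data$procedure)) +
    ggplot2::geom_step(direction = "mid") +
    ggplot2::geom_point(ggplot2::aes(shape = .data$observed), size = 2.5) +
    ggplot2::scale_shape_manual(values = c(`TRUE` = 16, `FALSE` = 1),
                                labels = c(`TRUE` = "observed", `FALSE` = "extrapolated"),
                                name = NULL) +
    ggplot2::scale_x_continuous(breaks = 7:14) +
    ggplot2::labs(x = "DRS total", y = "Remission probability",
                  colour = "Procedure",
                  title = "Remission probability bands by procedure") +
    ggplot2::theme_minimal()
}

#' Plot reconstructed score distributions
#'
#' Bar chart of the per-score counts for each solution, split into remitting
#' and non-remitting patients. With many solutions, only the first
#' `max_solutions` are shown.
#'
#' @param object A [reconstruct_score_distribution()] result.
#' @param max_solutions Facet at most this many solutions.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.drs_reconstruction <- function(object, max_solutions = 6, ...) {
  long <- tidy(object)
  if (!nrow(long)) abort("Nothing to plot: the reconstruction has no solutions.")
  keep <- head(unique(long$solution_id), max_solutions)
  long <- long[long$solution_id %in% keep, ]
  long <- tidyr::pivot_longer(
    dplyr::mutate(long, no_remission = .data$count - .data$remitters),
    cols = c("remitters", "no_remission"),
    names_to = "group", values_to = "patients"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$drs_total, y = .data$patients,
                                     fill = .data$group)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~solution_id, labeller = ggplot2::label_both) +
    ggplot2::scale_x_continuous(breaks = unique(long$drs_total)) +
    ggplot2::labs(x = "DRS total", y = "Patients", fill = NULL,
                  title = sprintf("Reconstructed %s score distributions",
                                  object$constraints$label)) +
    ggplot2::theme_minimal()
}

#' Plot DRS distributions by remission status
#'
#' @param object A `drs_comparison` from [compare_remission_groups()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.drs_comparison <- function(object, ...) {
  ggplot2::ggplot(object$summaries,
                  ggplot2::aes(x = .data$group, y = .data$mean,
                               ymin = .data$mean - .data$sd,
                               ymax = .data$mean + .data$sd,
                               colour = .data$group)) +
    ggplot2::geom_pointrange() +
    ggplot2::facet_wrap(~procedure) +
    ggplot2::labs(x = NULL, y = "DRS (mean ± SD)",
                  title = "DRS by remission status") +
    ggplot2::guides(colour = "none") +
    ggplot2::theme_minimal()
}
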