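#' Load the per-procedure remission band model
#'
#' The band model maps a total DRS and a procedure to the probability of
#' diabetes remission observed in the derivation cohort:
#'
#' * IISG: DRS 7-8 -> 1.00, DRS 9 -> 0.35, DRS >= 10 -> 0.00;
#' * IIDSG: DRS 8-10 -> 1.00, DRS 11 -> 0.55, DRS >= 12 -> 0.00.
#'
#' Two edge choices are deliberate. The IIDSG no-remission cut-off is DRS
#' >= 12 (the empirical statement), even though a looser "more than 12"
#' phrasing also circulates. A DRS of 7 under IIDSG falls below the observed
#' IIDSG range (8-14); the band still returns 1.0 but the prediction is
#' flagged as extrapolated, never silently returned. Probabilities within a
#' procedure are non-increasing in the score; the intermediate values (0.35,
#' 0.55) are empirical cohort rates, not smoothed model output.
#'
#' Band edges and probabilities live in a plain JSON file shipped with the
#' package so users can substitute their own calibration.
#'
#' @param path Optional path to a JSON band-model file; defaults to the
#'   configuration shipped with the package.
#' @return An object of class `drs_outcome_model`: a tibble of bands
#'   (`procedure`, `from`, `to`, `prob`) with the observed score ranges and
#'   recommendation windows as attributes.
#' @examples
#' model <- drs_outcome_model()
#' model
#' @export
drs_outcome_model <- function(path = NULL) {
  path <- path %||% system.file("extdata", "outcome_bands.json", package = "drscore")
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  bands <- dplyr::bind_rows(
    tibble::as_tibble(cfg$bands$IISG) |> dplyr::mutate(procedure = "IISG"),
    tibble::as_tibble(cfg$bands$IIDSG) |> dplyr::mutate(procedure = "IIDSG")
  ) |>
    dplyr::select("procedure", "from", "to", "prob")
  validate_band_model(bands)
  structure(
    bands,
    observed_range = cfg$observed_range,
    recommendation = cfg$recommendation,
    class = c("drs_outcome_model", class(bands))
  )
}

validate_band_model <- function(bands) {
  for (proc in procedures) {
    b <- bands[bands$procedure == proc, ]
    b <- b[order(b$from), ]
    covered <- unlist(Map(seq, b$from, b$to))
    if (!identical(sort(covered), 7:14)) {
      abort(sprintf("Bands for %s must tile the scores 7-14 without gaps or overlap.", proc))
    }
    if (any(b$prob < 0 | b$prob > 1)) {
      abort("Band probabilities must lie in [0, 1].")
    }
    per_score <- b$prob[findInterval(7:14, b$from)]
    if (any(diff(per_score) > 0)) {
      abort(sprintf("Band probabilities for %s must be non-increasing in the score.", proc))
    }
  }
  invisible(bands)
}

#' Remission probability for a DRS total under a procedure
#'
#' @param drs_total Integer vector of total scores (7-14).
#' @param procedure Character vector, `"IISG"` or `"IIDSG"` (recycled).
#' @param model A [drs_outcome_model()].
#' @param warn_extrapolation Warn when a score falls outside the procedure's
#'   observed range (e.g. DRS 7 under IIDSG)? The returned attribute
#'   `"extrapolated"` carries the same flags either way.
#' @return Numeric vector of remission probabilities, with a logical
#'   attribute `"extrapolated"`.
#' @examples
#' predict_remission(c(8, 9, 12), "IISG")
#' predict_remission(11, "IIDSG")
#' @export
predict_remission <- function(drs_total, procedure, model = drs_outcome_model(),
                              warn_extrapolation = TRUE) {
  check_drs_total(drs_total)
  if (!all(procedure %in% procedures)) {
    abort(sprintf("`procedure` must be one of %s.",
                  paste0('"', procedures, '"', collapse = ", ")))
  }
  n <- max(length(drs_total), length(procedure))
  drs_total <- rep_len(drs_total, n)
  procedure <- rep_len(procedure, n)

  prob <- numeric(n)
  extrapolated <- logical(n)
  ranges <- attr(model, "observed_range")
  for (proc in unique(procedure)) {
    idx <- procedure == proc
    b <- model[model$procedure == proc, ]
    b <- b[order(b$from), ]
    prob[idx] <- b$prob[findInterval(drs_total[idx], b$from)]
    rng <- ranges[[proc]]
    extrapolated[idx] <- drs_total[idx] < rng[1] | drs_total[idx] > rng[2]
  }
  if (warn_extrapolation && any(extrapolated)) {
    warn(sprintf(
      "DRS %s outside the observed range for %s; band probability is an extrapolation.",
      paste(unique(drs_total[extrapolated]), collapse = ", "),
      paste(unique(procedure[extrapolated]), collapse = ", ")
    ))
  }
  structure(prob, extrapolated = extrapolated)
}

#' Recommend a procedure from the DRS total
#'
#' Encodes the derivation study's selection guidance: DRS 7-8 patients
#' should only have IISG; IIDSG may be taken up for a DRS up to 11; at DRS
#' 12-14 remission is not expected under either studied procedure, so the
#' recommendation is `"neither"`. The mapping coincides with the severity
#' grades (grade 1 -> IISG, grade 2 -> IIDSG, grade 3 -> neither).
#'
#' @inheritParams predict_remission
#' @return Character vector: `"IISG"`, `"IIDSG"` or `"neither"`.
#' @examples
#' recommend_procedure(7:14)
#' @export
recommend_procedure <- function(drs_total, model = drs_outcome_model()) {
  check_drs_total(drs_total)
  rec <- attr(model, "recommendation")
  out <- rep(NA_character_, length(drs_total))
  for (choice in names(rec)) {
    rng <- rec[[choice]]
    out[drs_total >= rng[1] & drs_total <= rng[2]] <- choice
  }
  out
}

#' Attach remission predictions to a scored cohort
#'
#' Adds `remission_prob` (from the patient's own procedure when a
#' `procedure` column is present, otherwise from the recommended procedure),
#' `recommended_procedure`, and an `extrapolated` flag.
#'
#' @param scored Data frame with a `drs_total` column, e.g. from
#'   [drs_score()]; an optional `procedure` column selects the band set per
#'   patient.
#' @param model A [drs_outcome_model()].
#' @return The input tibble plus `remission_prob`, `recommended_procedure`
#'   and `extrapolated`.
#' @examples
#' tibble::tibble(drs_total = c(8, 9, 11), procedure = c("IISG", "IISG", "IIDSG")) |>
#'   drs_predict()
#' @export
drs_predict <- function(scored, model = drs_outcome_model()) {
  stopifnot(is.data.frame(scored))
  if (!"drs_total" %in% names(scored)) {
    abort("`scored` must have a `drs_total` column; run drs_score() first.")
  }
  out <- tibble::as_tibble(scored)
  out$recommended_procedure <- recommend_procedure(out$drs_total, model)
  proc <- if ("procedure" %in% names(out)) {
    as.character(out$procedure)
  } else {
    # fall back to the recommended procedure; severe scores get IISG bands
    # (both procedures assign probability zero there, so the choice is moot)
    ifelse(out$recommended_procedure == "neither", "IISG", out$recommended_procedure)
  }
  prob <- predict_remission(out$drs_total, proc, model, warn_extrapolation = FALSE)
  out$remission_prob <- as.numeric(prob)
  out$extrapolated <- attr(prob, "extrapolated")
  out
}
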