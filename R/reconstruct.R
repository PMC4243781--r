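#' Aggregate constraint set for score-distribution reconstruction
#'
#' Describes everything a published results section asserts about the
#' distribution of an integer score in a cohort: size, mean and SD (within a
#' tolerance mirroring one-decimal rounding), observed score range, total
#' number of remitters, the band structure of remission (scores that all
#' remitted, the single partial score with its printed percentage, scores
#' with no remission), and optionally the remitter / non-remitter subgroup
#' means and SDs. [reconstruct_score_distribution()] then enumerates every
#' integer count vector satisfying the set.
#'
#' @param score_range Integer vector `c(lo, hi)`, the observed score range.
#' @param n Cohort size (<= 200; together with a range width <= 8 this keeps
#'   exhaustive search tractable).
#' @param mean,sd Printed mean and SD of the score (n - 1 denominator for
#'   the overall SD).
#' @param mean_tol,sd_tol Tolerances around `mean` / `sd`; the default 0.05
#'   mirrors one-decimal rounding. Subgroup moments use the same tolerances.
#' @param remission_total Exact number of remitters, or `NA` to drop all
#'   remission constraints.
#' @param full_remission_scores Scores at which every patient remitted.
#' @param partial_score The single score with a fractional remission rate,
#'   or `NA`. Remission at higher scores is zero. The number of remitters at
#'   the partial score is forced by arithmetic: `remission_total` minus the
#'   patients at `full_remission_scores`.
#' @param partial_pct Printed remission percentage at `partial_score`; a
#'   solution must make the achieved ratio round (half-up) to this whole
#'   percentage, or `NA` to skip the rounding rule.
#' @param remitter_mean,remitter_sd,nonremitter_mean,nonremitter_sd Printed
#'   subgroup moments, or `NA` to drop them. Because the publication never
#'   states which SD denominator the subgroup tables used, a subgroup SD
#'   matches when either the n - 1 or the n form falls within tolerance, and
#'   the accepted form(s) are reported per solution.
#' @param endpoints_observed Require at least one patient at each end of
#'   `score_range` (a printed range implies both endpoints were seen)?
#' @param label Optional label (e.g. the procedure) carried into solutions.
#' @return Object of class `drs_constraints`.
#' @seealso [drs_constraints_iisg()], [drs_constraints_iidsg()] for the
#'   packaged study constraint sets.
#' @export
drs_constraints <- function(score_range, n, mean, sd,
                            mean_tol = 0.05, sd_tol = 0.05,
                            remission_total = NA,
                            full_remission_scores = integer(),
                            partial_score = NA, partial_pct = NA,
                            remitter_mean = NA, remitter_sd = NA,
                            nonremitter_mean = NA, nonremitter_sd = NA,
                            endpoints_observed = TRUE, label = NULL) {
  stopifnot(length(score_range) == 2, score_range[1] <= score_range[2])
  width <- score_range[2] - score_range[1] + 1
  if (n > 200 || width > 8) {
    abort("Exhaustive search requires n <= 200 and a score-range width <= 8.")
  }
  if (!is.na(remission_total)) {
    if (length(full_remission_scores) &&
        any(full_remission_scores < score_range[1] | full_remission_scores > score_range[2])) {
      abort("`full_remission_scores` must lie inside `score_range`.")
    }
    if (!is.na(partial_score) && length(full_remission_scores) &&
        any(full_remission_scores >= partial_score)) {
      abort("`full_remission_scores` must lie below `partial_score`.")
    }
  }
  structure(
    list(
      score_range = as.integer(score_range), n = as.integer(n),
      mean = mean, sd = sd, mean_tol = mean_tol, sd_tol = sd_tol,
      remission_total = remission_total,
      full_remission_scores = as.integer(full_remission_scores),
      partial_score = partial_score, partial_pct = partial_pct,
      remitter_mean = remitter_mean, remitter_sd = remitter_sd,
      nonremitter_mean = nonremitter_mean, nonremitter_sd = nonremitter_sd,
      endpoints_observed = endpoints_observed,
      label = label %||% "cohort"
    ),
    class = "drs_constraints"
  )
}

published_aggregates <- function(path = NULL) {
  path <- path %||% system.file("extdata", "published_aggregates.json", package = "drscore")
  jsonlite::read_json(path, simplifyVector = TRUE)
}

constraints_from_block <- function(block, subgroup_moments, label) {
  drs_constraints(
    score_range = block$score_range, n = block$n,
    mean = block$mean, sd = block$sd,
    remission_total = block$remission_total,
    full_remission_scores = block$full_remission_scores,
    partial_score = block$partial_score, partial_pct = block$partial_pct,
    remitter_mean = if (subgroup_moments) block$remitter$mean else NA,
    remitter_sd = if (subgroup_moments) block$remitter$sd else NA,
    nonremitter_mean = if (subgroup_moments) block$nonremitter$mean else NA,
    nonremitter_sd = if (subgroup_moments) block$nonremitter$sd else NA,
    label = label
  )
}

#' Packaged constraint sets for the two study cohorts
#'
#' `drs_constraints_iisg()` encodes the printed IISG aggregates (n 46, DRS
#' 9.2 +/- 1.4, range 7-13, 21 remitters, all DRS 7-8 remitted, 35% at DRS
#' 9, none at DRS >= 10) and `drs_constraints_iidsg()` the IIDSG ones (n 29,
#' 10.4 +/- 1.3, range 8-14, 21 remitters, all DRS 8-10 remitted, 55% at
#' DRS 11, none at DRS >= 12).
#'
#' `subgroup_moments` controls whether the remitter / non-remitter means and
#' SDs are also imposed. The full set (`TRUE`) reproduces every printed
#' aggregate -- and is, provably, infeasible at the default +/- 0.05
#' tolerances: exhaustive enumeration shows the partial-score percentage
#' rule cannot coexist with the printed subgroup moments in either cohort
#' (see the methods vignette). The core set (`FALSE`) drops the subgroup
#' moments -- the aggregates whose printed values are duplicated verbatim in
#' the publication's BMI-stratified table and are therefore the least
#' trustworthy -- and admits solutions; the remission split is still pinned
#' exactly by the remission total and band rules.
#'
#' @param subgroup_moments Impose the remitter / non-remitter means and SDs?
#' @return A [drs_constraints()] object.
#' @export
drs_constraints_iisg <- function(subgroup_moments = TRUE) {
  constraints_from_block(published_aggregates()$IISG, subgroup_moments, "IISG")
}

#' @rdname drs_constraints_iisg
#' @export
drs_constraints_iidsg <- function(subgroup_moments = TRUE) {
  constraints_from_block(published_aggregates()$IIDSG, subgroup_moments, "IIDSG")
}

# moments of a counts vector over scores, via running sums
counts_moments <- function(counts, scores, ddof = 1) {
  n <- sum(counts)
  s <- sum(counts * scores)
  ss <- sum(counts * scores^2)
  m <- s / n
  var <- (ss - n * m^2) / (n - ddof)
  list(n = n, mean = m, sd = sqrt(pmax(var, 0)))
}

#' Reconstruct feasible score distributions from printed aggregates
#'
#' Exhaustively enumerates every vector of non-negative integer counts over
#' the score range that sums to the cohort size and satisfies the whole
#' constraint set: overall mean and SD within tolerance, observed range
#' endpoints, exact remitter total, band-rule remission split with the
#' partial-score percentage rounding rule, and (when present) subgroup
#' means/SDs within tolerance. The search is depth-first over counts in
#' ascending score order with branch-and-bound pruning on the achievable
#' score sum and sum of squares, plus early rejection of remitter-side
#' constraints once the partial score is fixed; results are therefore
#' returned in lexicographic count order, and an empty result is a proof of
#' infeasibility, not a sampling failure.
#'
#' Every returned solution is re-validated by [check_reconstruction()], an
#' evaluator that expands the counts into raw score vectors and recomputes
#' all statistics directly.
#'
#' @param constraints A [drs_constraints()] object.
#' @param max_solutions Stop after this many solutions (default: keep all).
#' @return Object of class `drs_reconstruction`: a list with `solutions`
#'   (tibble: one row per solution with a `counts` list-column, remitters at
#'   the partial score, achieved moments, and which SD denominator(s) the
#'   subgroups matched under) and the `constraints`. `tidy()` gives the
#'   long per-score counts, `glance()` a one-row feasibility summary.
#' @examples
#' # forced solution: 3 patients, mean 8, sd 1 over scores 7-9
#' toy <- drs_constraints(c(7, 9), n = 3, mean = 8, sd = 1)
#' tidy(reconstruct_score_distribution(toy))
#' @export
reconstruct_score_distribution <- function(constraints, max_solutions = Inf) {
  if (!inherits(constraints, "drs_constraints")) {
    abort("`constraints` must come from drs_constraints().")
  }
  cn <- constraints
  scores <- seq(cn$score_range[1], cn$score_range[2])
  k <- length(scores)
  n <- cn$n

  s_min <- n * (cn$mean - cn$mean_tol)
  s_max <- n * (cn$mean + cn$mean_tol)
  var_lo <- max(0, cn$sd - cn$sd_tol)^2
  var_hi <- (cn$sd + cn$sd_tol)^2
  ss_min <- (n - 1) * var_lo + s_min^2 / n
  ss_max <- (n - 1) * var_hi + s_max^2 / n

  has_remission <- !is.na(cn$remission_total)
  partial_idx <- if (has_remission && !is.na(cn$partial_score)) {
    match(cn$partial_score, scores)
  } else NA_integer_
  full_idx <- match(cn$full_remission_scores, scores)

  solutions <- list()

  # remitter-side feasibility once counts up to the partial score are fixed
  remitter_ok <- function(counts_head) {
    full_count <- sum(counts_head[full_idx])
    cp <- if (!is.na(partial_idx)) counts_head[partial_idx] else 0L
    rp <- cn$remission_total - full_count
    if (rp < 0 || rp > cp) return(NULL)
    if (!is.na(cn$partial_pct) && cp > 0 &&
        round_half_up(100 * rp / cp) != cn$partial_pct) return(NULL)
    if (is.na(cn$partial_score) && rp != 0) return(NULL)
    rem_counts <- counts_head[full_idx]
    rem_scores <- scores[full_idx]
    if (!is.na(partial_idx)) {
      rem_counts <- c(rem_counts, rp)
      rem_scores <- c(rem_scores, scores[partial_idx])
    }
    denom_r <- character(0)
    if (!is.na(cn$remitter_mean) || !is.na(cn$remitter_sd)) {
      if (sum(rem_counts) == 0) return(NULL)
      mo1 <- counts_moments(rem_counts, rem_scores, ddof = 1)
      mo0 <- counts_moments(rem_counts, rem_scores, ddof = 0)
      if (!is.na(cn$remitter_mean) &&
          abs(mo1$mean - cn$remitter_mean) > cn$mean_tol) return(NULL)
      if (!is.na(cn$remitter_sd)) {
        if (abs(mo1$sd - cn$remitter_sd) <= cn$sd_tol) denom_r <- c(denom_r, "n-1")
        if (abs(mo0$sd - cn$remitter_sd) <= cn$sd_tol) denom_r <- c(denom_r, "n")
        if (!length(denom_r)) return(NULL)
      }
    }
    list(rp = rp, denom_r = denom_r)
  }

  check_full <- function(counts) {
    if (cn$endpoints_observed && (counts[1] == 0 || counts[k] == 0)) return()
    mo <- counts_moments(counts, scores, ddof = 1)
    if (abs(mo$mean - cn$mean) > cn$mean_tol) return()
    if (abs(mo$sd - cn$sd) > cn$sd_tol) return()

    rp <- NA_integer_; denom_r <- NA_character_; denom_n <- NA_character_
    if (has_remission) {
      rem <- remitter_ok(counts)
      if (is.null(rem)) return()
      rp <- rem$rp
      denom_r <- if (length(rem$denom_r)) paste(rem$denom_r, collapse = "&") else NA_character_

      non_counts <- counts
      non_counts[full_idx] <- 0L
      if (!is.na(partial_idx)) non_counts[partial_idx] <- counts[partial_idx] - rp
      denoms <- character(0)
      if (!is.na(cn$nonremitter_mean) || !is.na(cn$nonremitter_sd)) {
        if (sum(non_counts) == 0) return()
        mo1 <- counts_moments(non_counts, scores, ddof = 1)
        mo0 <- counts_moments(non_counts, scores, ddof = 0)
        if (!is.na(cn$nonremitter_mean) &&
            abs(mo1$mean - cn$nonremitter_mean) > cn$mean_tol) return()
        if (!is.na(cn$nonremitter_sd)) {
          if (abs(mo1$sd - cn$nonremitter_sd) <= cn$sd_tol) denoms <- c(denoms, "n-1")
          if (abs(mo0$sd - cn$nonremitter_sd) <= cn$sd_tol) denoms <- c(denoms, "n")
          if (!length(denoms)) return()
        }
      }
      denom_n <- if (length(denoms)) paste(denoms, collapse = "&") else NA_character_
    }

    solutions[[length(solutions) + 1L]] <<- list(
      counts = setNames(as.integer(counts), scores),
      partial_remitters = rp,
      mean = mo$mean, sd = mo$sd,
      remitter_sd_denominator = denom_r,
      nonremitter_sd_denominator = denom_n
    )
  }

  recurse <- function(i, counts, left, s_acc, ss_acc) {
    if (length(solutions) >= max_solutions) return()
    if (i == k) {
      s <- s_acc + left * scores[k]
      ss <- ss_acc + left * scores[k]^2
      if (s >= s_min && s <= s_max && ss >= ss_min - 1e-9 && ss <= ss_max + 1e-9) {
        counts[k] <- left
        check_full(counts)
      }
      return()
    }
    nxt <- scores[i + 1]
    hi <- scores[k]
    for (c_i in 0:left) {
      left_i <- left - c_i
      s_i <- s_acc + c_i * scores[i]
      ss_i <- ss_acc + c_i * scores[i]^2
      # achievable windows for the remaining counts
      if (s_i + left_i * nxt > s_max) next
      if (s_i + left_i * hi < s_min) break
      if (ss_i + left_i * nxt^2 > ss_max + 1e-9) next
      if (ss_i + left_i * hi^2 < ss_min - 1e-9) break
      counts[i] <- c_i
      # once every remission-relevant low score is fixed, vet the remitter side
      if (has_remission && !is.na(partial_idx) && i == partial_idx) {
        if (is.null(remitter_ok(counts[seq_len(i)]))) next
      }
      recurse(i + 1, counts, left_i, s_i, ss_i)
    }
  }

  recurse(1, integer(k), n, 0, 0)

  sol_tbl <- if (length(solutions)) {
    tibble::tibble(
      solution_id = seq_along(solutions),
      counts = purrr::map(solutions, "counts"),
      partial_remitters = purrr::map_int(solutions, ~ as.integer(.x$partial_remitters)),
      mean = purrr::map_dbl(solutions, "mean"),
      sd = purrr::map_dbl(solutions, "sd"),
      remitter_sd_denominator = purrr::map_chr(solutions, "remitter_sd_denominator"),
      nonremitter_sd_denominator = purrr::map_chr(solutions, "nonremitter_sd_denominator")
    )
  } else {
    tibble::tibble(
      solution_id = integer(), counts = list(), partial_remitters = integer(),
      mean = numeric(), sd = numeric(),
      remitter_sd_denominator = character(), nonremitter_sd_denominator = character()
    )
  }

  structure(list(solutions = sol_tbl, constraints = cn),
            class = "drs_reconstruction")
}

#' @export
print.drs_reconstruction <- function(x, ...) {
  cat(sprintf("Score-distribution reconstruction for %s: %d solution(s)\n",
              x$constraints$label, nrow(x$solutions)))
  if (nrow(x$solutions)) print(x$solutions)
  invisible(x)
}

#' Independently re-validate a reconstruction solution
#'
#' Expands a solution's counts into raw per-patient score vectors and checks
#' every constraint with direct `mean()` / `sd()` computations -- a separate
#' code path from the solver's incremental sums, serving as double-entry
#' verification.
#'
#' @param solution One row of the `solutions` tibble of a
#'   [reconstruct_score_distribution()] result (or a named count vector plus
#'   `partial_remitters`).
#' @param constraints The matching [drs_constraints()].
#' @return A tibble with one row per checked constraint: `constraint`,
#'   `achieved`, `target`, `tolerance`, `ok`.
#' @export
check_reconstruction <- function(solution, constraints) {
  cn <- constraints
  if (is.data.frame(solution)) {
    counts <- solution$counts[[1]]
    rp <- solution$partial_remitters[1]
  } else {
    counts <- solution$counts
    rp <- solution$partial_remitters
  }
  scores <- as.integer(names(counts))
  values <- rep(scores, counts)

  rows <- list(
    tibble::tibble(constraint = "n", achieved = length(values),
                   target = as.numeric(cn$n), tolerance = 0,
                   ok = length(values) == cn$n),
    tibble::tibble(constraint = "mean", achieved = mean(values),
                   target = cn$mean, tolerance = cn$mean_tol,
                   ok = abs(mean(values) - cn$mean) <= cn$mean_tol),
    tibble::tibble(constraint = "sd", achieved = sd(values),
                   target = cn$sd, tolerance = cn$sd_tol,
                   ok = abs(sd(values) - cn$sd) <= cn$sd_tol)
  )
  if (cn$endpoints_observed) {
    seen <- range(values)
    rows <- c(rows, list(tibble::tibble(
      constraint = "range", achieved = NA_real_, target = NA_real_, tolerance = 0,
      ok = seen[1] == cn$score_range[1] && seen[2] == cn$score_range[2]
    )))
  }
  if (!is.na(cn$remission_total)) {
    full <- values[values %in% cn$full_remission_scores]
    at_partial <- if (!is.na(cn$partial_score)) sum(values == cn$partial_score) else 0L
    remitters <- c(full, if (!is.na(cn$partial_score)) rep(cn$partial_score, rp))
    nonrem <- c(
      if (!is.na(cn$partial_score)) rep(cn$partial_score, at_partial - rp),
      values[!values %in% c(cn$full_remission_scores,
                            if (!is.na(cn$partial_score)) cn$partial_score)]
    )
    rows <- c(rows, list(tibble::tibble(
      constraint = "remission_total", achieved = length(remitters),
      target = as.numeric(cn$remission_total), tolerance = 0,
      ok = length(remitters) == cn$remission_total && rp >= 0 && rp <= at_partial
    )))
    if (!is.na(cn$partial_pct) && at_partial > 0) {
      pct <- round_half_up(100 * rp / at_partial)
      rows <- c(rows, list(tibble::tibble(
        constraint = "partial_pct", achieved = pct, target = cn$partial_pct,
        tolerance = 0, ok = pct == cn$partial_pct
      )))
    }
    sub_checks <- list(
      list("remitter_mean", remitters, cn$remitter_mean, cn$mean_tol, mean),
      list("nonremitter_mean", nonrem, cn$nonremitter_mean, cn$mean_tol, mean)
    )
    for (chk in sub_checks) {
      if (!is.na(chk[[3]])) {
        achieved <- chk[[5]](chk[[2]])
        rows <- c(rows, list(tibble::tibble(
          constraint = chk[[1]], achieved = achieved, target = chk[[3]],
          tolerance = chk[[4]], ok = abs(achieved - chk[[3]]) <= chk[[4]]
        )))
      }
    }
    sd_pop <- function(v) sqrt(mean((v - mean(v))^2))
    for (chk in list(list("remitter_sd", remitters, cn$remitter_sd),
                     list("nonremitter_sd", nonrem, cn$nonremitter_sd))) {
      if (!is.na(chk[[3]])) {
        s1 <- sd(chk[[2]]); s0 <- sd_pop(chk[[2]])
        ok <- (is.finite(s1) && abs(s1 - chk[[3]]) <= cn$sd_tol) ||
          abs(s0 - chk[[3]]) <= cn$sd_tol
        rows <- c(rows, list(tibble::tibble(
          constraint = chk[[1]], achieved = s1, target = chk[[3]],
          tolerance = cn$sd_tol, ok = ok
        )))
      }
    }
  }
  dplyr::bind_rows(rows)
}

#' Expand a reconstruction solution into a patient-level cohort
#'
#' Turns a solution's per-score counts and remission split into one row per
#' patient, ready for [compare_remission_groups()].
#'
#' @param reconstruction A [reconstruct_score_distribution()] result with at
#'   least one solution.
#' @param solution_id Which solution to expand (default: the first, i.e.
#'   lexicographically smallest).
#' @return Tibble with `patient_id`, `procedure` (the constraint label),
#'   `drs_total` and `remission`.
#' @export
reconstruction_cohort <- function(reconstruction, solution_id = 1) {
  stopifnot(inherits(reconstruction, "drs_reconstruction"))
  sols <- reconstruction$solutions
  if (!nrow(sols)) abort("The reconstruction has no solutions to expand.")
  row <- sols[sols$solution_id == solution_id, ]
  if (!nrow(row)) abort(sprintf("No solution with id %s.", solution_id))
  cn <- reconstruction$constraints
  counts <- row$counts[[1]]
  scores <- as.integer(names(counts))
  total <- rep(scores, counts)
  remission <- logical(length(total))
  remission[total %in% cn$full_remission_scores] <- TRUE
  if (!is.na(cn$partial_score) && row$partial_remitters[1] > 0) {
    idx <- which(total == cn$partial_score)
    remission[idx[seq_len(row$partial_remitters[1])]] <- TRUE
  }
  tibble::tibble(
    patient_id = sprintf("%s-R%03d", cn$label, seq_along(total)),
    procedure = cn$label,
    drs_total = total,
    remission = remission
  )
}
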