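test_that("a fully determined toy constraint set has its unique forced solution", {
  # 3 patients on 7-9 with mean 8 and sd 1 can only be {7, 8, 9}
  toy <- drs_constraints(c(7, 9), n = 3, mean = 8, sd = 1)
  rec <- reconstruct_score_distribution(toy)
  expect_equal(nrow(rec$solutions), 1)
  expect_equal(rec$solutions$counts[[1]], c(`7` = 1L, `8` = 1L, `9` = 1L))
  expect_true(all(check_reconstruction(rec$solutions[1, ], toy)$ok))
})

test_that("a contradictory constraint set returns an empty solution list", {
  # 21 remitters demanded but the all-remit band can hold at most 5 patients
  bad <- drs_constraints(c(9, 11), n = 5, mean = 10, sd = 1,
                         remission_total = 21,
                         full_remission_scores = 9, partial_score = 10,
                         endpoints_observed = FALSE)
  rec <- reconstruct_score_distribution(bad)
  expect_equal(nrow(rec$solutions), 0)
  expect_false(glance(rec)$feasible)
})

test_that("intractable problems are rejected before the search starts", {
  expect_error(drs_constraints(c(7, 14), n = 500, mean = 9, sd = 1), "n <= 200")
  expect_error(drs_constraints(c(1, 14), n = 50, mean = 9, sd = 1), "width <= 8")
  expect_error(reconstruct_score_distribution(list()), "drs_constraints")
})

test_that("core study constraint sets are feasible and solution counts match the exhaustive oracle", {
  # frozen counts from an independent exhaustive enumeration
  iisg <- reconstruct_score_distribution(drs_constraints_iisg(subgroup_moments = FALSE))
  expect_equal(nrow(iisg$solutions), 485)
  iidsg <- reconstruct_score_distribution(drs_constraints_iidsg(subgroup_moments = FALSE))
  expect_equal(nrow(iidsg$solutions), 17)

  # lexicographic ordering of solutions by count vector
  first_counts <- do.call(rbind, iisg$solutions$counts)
  ord <- do.call(order, as.data.frame(first_counts))
  expect_equal(ord, seq_len(nrow(first_counts)))
})

test_that("every returned solution passes the independent constraint evaluator (double entry)", {
  cn <- drs_constraints_iidsg(subgroup_moments = FALSE)
  rec <- reconstruct_score_distribution(cn)
  for (i in seq_len(nrow(rec$solutions))) {
    checks <- check_reconstruction(rec$solutions[i, ], cn)
    expect_true(all(checks$ok), info = sprintf("solution %d", i))
  }
})

test_that("solutions respect the hard structural constraints", {
  cn <- drs_constraints_iisg(subgroup_moments = FALSE)
  rec <- reconstruct_score_distribution(cn)
  for (i in seq_len(nrow(rec$solutions))) {
    counts <- rec$solutions$counts[[i]]
    expect_equal(sum(counts), 46L)
    expect_gte(counts[["7"]], 1L)   # printed range endpoints observed
    expect_gte(counts[["13"]], 1L)
    rp <- rec$solutions$partial_remitters[i]
    expect_equal(counts[["7"]] + counts[["8"]] + rp, 21L)
    if (counts[["9"]] > 0) {
      expect_equal(round_half_up(100 * rp / counts[["9"]]), 35)
    } else {
      expect_equal(rp, 0L)  # the percentage rule is vacuous without DRS-9 patients
    }
  }
})

test_that("reconstruction cohorts reproduce the published remission rates", {
  iisg <- reconstruction_cohort(
    reconstruct_score_distribution(drs_constraints_iisg(subgroup_moments = FALSE))
  )
  expect_equal(nrow(iisg), 46)
  expect_equal(sum(iisg$remission), 21)
  cmp <- compare_remission_groups(iisg)
  expect_equal(cmp$by_procedure$remission_rate_pct, 46)

  iidsg <- reconstruction_cohort(
    reconstruct_score_distribution(drs_constraints_iidsg(subgroup_moments = FALSE))
  )
  expect_equal(compare_remission_groups(iidsg)$by_procedure$remission_rate_pct, 72)
})

test_that("tidy and glance expose reconstruction results in long form", {
  rec <- reconstruct_score_distribution(drs_constraints_iidsg(subgroup_moments = FALSE))
  long <- tidy(rec)
  expect_setequal(names(long), c("solution_id", "drs_total", "count", "remitters"))
  per_sol <- long |>
    dplyr::group_by(.data$solution_id) |>
    dplyr::summarise(n = sum(.data$count), rem = sum(.data$remitters))
  expect_true(all(per_sol$n == 29))
  expect_true(all(per_sol$rem == 21))
  g <- glance(rec)
  expect_true(g$feasible)
  expect_equal(g$n_solutions, 17)
})

test_that("expanding a missing solution fails cleanly", {
  rec <- reconstruct_score_distribution(
    drs_constraints(c(9, 11), n = 5, mean = 10, sd = 1, remission_total = 21,
                    full_remission_scores = 9, partial_score = 10,
                    endpoints_observed = FALSE)
  )
  expect_error(reconstruction_cohort(rec), "no solutions")
})
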