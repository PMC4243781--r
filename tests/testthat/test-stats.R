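test_that("drs_summarize matches closed forms", {
  expect_equal(drs_summarize(c(7, 7, 7)),
               tibble::tibble(n = 3L, mean = 7, sd = 0, min = 7, max = 7))
  s <- drs_summarize(c(8, 10))
  expect_equal(s$mean, 9)
  expect_equal(s$sd, sqrt(2))
  expect_error(drs_summarize(numeric(0)), "non-empty")
  expect_error(drs_summarize(c(1, NA)), "finite")
})

test_that("summary-based t-test equals the raw-data t-test (oracle equivalence)", {
  withr::with_seed(11, {
    for (rep in 1:200) {
      n1 <- sample(3:12, 1); n2 <- sample(3:12, 1)
      x <- rnorm(n1, mean = runif(1, -2, 2), sd = runif(1, 0.5, 3))
      y <- rnorm(n2, mean = runif(1, -2, 2), sd = runif(1, 0.5, 3))
      for (variant in c("welch", "pooled")) {
        ours <- drs_t_test(drs_summarize(x), drs_summarize(y), variant)
        ref <- t.test(x, y, var.equal = variant == "pooled")
        expect_equal(ours$t_statistic, unname(ref$statistic), tolerance = 1e-12)
        expect_equal(ours$degrees_of_freedom, unname(ref$parameter), tolerance = 1e-12)
        expect_equal(ours$p_value, ref$p.value, tolerance = 1e-12)
      }
    }
  })
})

test_that("t-test is symmetric in its groups and degenerate cases follow convention", {
  g <- list(n = 10, mean = 5, sd = 1)
  same <- drs_t_test(g, g)
  expect_equal(same$t_statistic, 0)
  expect_equal(same$p_value, 1)

  a <- list(n = 8, mean = 4, sd = 1.2); b <- list(n = 14, mean = 6, sd = 2.1)
  for (variant in c("welch", "pooled")) {
    ab <- drs_t_test(a, b, variant); ba <- drs_t_test(b, a, variant)
    expect_equal(ab$p_value, ba$p_value)
    expect_equal(ab$t_statistic, -ba$t_statistic)
    expect_gte(ab$p_value, 0); expect_lte(ab$p_value, 1)
  }

  # both SDs zero: p = 1 for equal means (by convention), 0 otherwise
  z <- drs_t_test(list(n = 5, mean = 2, sd = 0), list(n = 5, mean = 2, sd = 0))
  expect_equal(z$p_value, 1)
  z2 <- drs_t_test(list(n = 5, mean = 2, sd = 0), list(n = 5, mean = 3, sd = 0))
  expect_equal(z2$p_value, 0)
  expect_error(drs_t_test(list(n = 1, mean = 2, sd = 0), g), "n >= 2")
})

test_that("pooled and Welch agree exactly for balanced groups with equal SDs", {
  g1 <- list(n = 12, mean = 9.1, sd = 1.3)
  g2 <- list(n = 12, mean = 10.0, sd = 1.3)
  expect_equal(drs_t_test(g1, g2, "pooled")$p_value,
               drs_t_test(g1, g2, "welch")$p_value, tolerance = 1e-12)
  expect_equal(drs_t_test(g1, g2, "pooled")$degrees_of_freedom,
               drs_t_test(g1, g2, "welch")$degrees_of_freedom, tolerance = 1e-12)
})

test_that("published between-group and within-group comparisons are recovered", {
  between <- drs_t_test(list(n = 46, mean = 9.2, sd = 1.4),
                        list(n = 29, mean = 10.4, sd = 1.3), "welch")
  expect_equal(round(between$p_value, 4), 0.0004)
  within <- drs_t_test(list(n = 21, mean = 8.1, sd = 0.8),
                       list(n = 25, mean = 10.2, sd = 0.9), "pooled")
  expect_lt(within$p_value, 0.0001)
})

test_that("compare_remission_groups reports per-stratum summaries, rates and tests", {
  cohort <- tibble::tibble(
    procedure = "IISG",
    drs_total = c(rep(8L, 4), rep(11L, 4)),
    remission = rep(c(TRUE, FALSE), each = 4)
  )
  cmp <- compare_remission_groups(cohort)
  expect_equal(cmp$by_procedure$remission_rate_pct, 50)
  sm <- cmp$summaries
  expect_equal(sm$mean[sm$group == "remission"], 8)
  expect_equal(sm$mean[sm$group == "no_remission"], 11)
  expect_equal(cmp$n_tests, 1)
  expect_false(cmp$by_procedure$test_skipped)

  # a stratum with < 2 in one group is flagged, not tested
  small <- tibble::tibble(procedure = "IIDSG", drs_total = c(9L, 10L, 12L),
                          remission = c(TRUE, FALSE, FALSE))
  cmp2 <- compare_remission_groups(small)
  expect_true(cmp2$by_procedure$test_skipped)
  expect_equal(cmp2$n_tests, 0)
})

test_that("percentages round half up as in published tables", {
  expect_equal(round_half_up(100 * 21 / 46), 46)
  expect_equal(round_half_up(100 * 21 / 29), 72)
  expect_equal(round_half_up(0.5), 1)
  expect_equal(round_half_up(-0.5), -1)
  expect_equal(round_half_up(45.65, 1), 45.7)
})

test_that("tidiers return broom-shaped tibbles", {
  tt <- drs_t_test(list(n = 46, mean = 9.2, sd = 1.4),
                   list(n = 29, mean = 10.4, sd = 1.3))
  td <- tidy(tt)
  expect_named(td, c("estimate", "statistic", "parameter", "p.value", "method"))
  expect_equal(td$estimate, -1.2)
  cohort <- tibble::tibble(procedure = "IISG",
                           drs_total = c(8L, 8L, 11L, 11L),
                           remission = c(TRUE, TRUE, FALSE, FALSE))
  cmp <- compare_remission_groups(cohort)
  expect_s3_class(tidy(cmp), "tbl_df")
  expect_equal(nrow(glance(cmp)), 1)
})
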