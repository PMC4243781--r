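#' Generator configuration for synthetic cohorts
#'
#' Builds the configuration for [generate_cohort()]. The shipped defaults
#' emulate the derivation cohorts: raw preoperative fields follow truncated
#' normal distributions with the published means and SDs, truncated at the
#' eligibility bounds; each of the seven DRS components is unfavourable with
#' a frozen calibrated probability; and the component states share an
#' exchangeable latent "severity" correlation `rho` (a Gaussian copula
#' threshold model) so that the per-cohort SD of the total matches the
#' published spread, which independent components cannot reach.
#'
#' The calibration was performed once, against the published cohort
#' aggregates, and frozen in `inst/extdata/generator_defaults.json`; the
#' defaults are synthetic emulation parameters, not estimates of the real
#' per-component prevalences.
#'
#' @param procedure `"IISG"` or `"IIDSG"`; selects the default block.
#' @param n Cohort size (default: the study's group size).
#' @param seed Optional integer; a default seed recorded in the config and
#'   used by [generate_cohort()] when no seed is passed there.
#' @param p_unfavourable Optional named numeric vector overriding any of the
#'   seven component probabilities (`age`, `bmi`, `duration`, `micro`,
#'   `macro`, `insulin`, `cpeptide`), each in `[0, 1]`.
#' @param rho Latent severity correlation in `[0, 1)`.
#' @param remission Remission mechanism: `"band_model"` draws each patient's
#'   remission from the band probability at their DRS (so band rules hold by
#'   construction), `"logistic"` uses `plogis(beta0 + beta1 * drs_total)`.
#' @param beta0,beta1 Logistic mechanism coefficients (used when
#'   `remission = "logistic"`).
#' @param path Optional path to an alternative defaults JSON.
#' @return Object of class `drs_generator_config`.
#' @examples
#' cfg <- drs_generator_config("IISG", n = 10)
#' cfg$p_unfavourable
#' @export
drs_generator_config <- function(procedure, n = NULL, seed = NULL,
                                 p_unfavourable = NULL, rho = NULL,
                                 remission = c("band_model", "logistic"),
                                 beta0 = 18, beta1 = -2, path = NULL) {
  check_procedure(procedure)
  remission <- match.arg(remission)
  path <- path %||% system.file("extdata", "generator_defaults.json", package = "drscore")
  defaults <- jsonlite::read_json(path, simplifyVector = TRUE)
  block <- defaults[[procedure]]

  p <- unlist(block$p_unfavourable)
  if (!is.null(p_unfavourable)) {
    unknown <- setdiff(names(p_unfavourable), names(p))
    if (length(unknown)) {
      abort(sprintf("Unknown component(s) in `p_unfavourable`: %s.",
                    paste(unknown, collapse = ", ")))
    }
    p[names(p_unfavourable)] <- p_unfavourable
  }
  if (any(p < 0 | p > 1)) abort("Component probabilities must lie in [0, 1].")
  rho <- rho %||% block$rho
  if (rho < 0 || rho >= 1) abort("`rho` must lie in [0, 1).")
  n <- n %||% block$n
  if (!is.numeric(n) || n < 1 || n != round(n)) abort("`n` must be a positive integer.")

  marg <- block$marginals
  bounds <- block$bounds
  for (nm in names(marg)) {
    if (marg[[nm]]$sd < 0) abort(sprintf("Marginal sd for `%s` must be >= 0.", nm))
  }
  # the favourable component state must be reachable inside the eligibility
  # bounds, otherwise the config cannot be realised
  if (bounds$age[1] > 60 || bounds$age[2] < 30) {
    abort("Infeasible config: the age bounds exclude the favourable window [30, 60].")
  }
  if (bounds$bmi[2] < 27) {
    abort("Infeasible config: the BMI bounds exclude the favourable range >= 27.")
  }
  if (bounds$cpeptide[2] < 4) {
    abort("Infeasible config: the C-peptide bounds exclude the favourable range >= 4.")
  }
  if (bounds$duration[1] >= 10 && any(p["duration"] < 1)) {
    abort("Infeasible config: favourable duration (< 10 y) unreachable within bounds.")
  }

  structure(
    list(
      procedure = procedure, n = as.integer(n), seed = seed,
      p_unfavourable = p, rho = rho,
      marginals = marg, bounds = bounds,
      followup = defaults$followup,
      remission = remission, beta0 = beta0, beta1 = beta1
    ),
    class = "drs_generator_config"
  )
}

# inverse-CDF sampler for a normal truncated to (lo, hi)
rtruncnorm <- function(n, mean, sd, lo, hi) {
  plo <- pnorm(lo, mean, sd)
  phi <- pnorm(hi, mean, sd)
  if (phi - plo <= 0) {
    abort(sprintf("Truncation (%s, %s) carries no probability mass for N(%s, %s).",
                  lo, hi, mean, sd))
  }
  qnorm(runif(n, plo, phi), mean, sd)
}

# sample from a normal truncated to a union of disjoint intervals, choosing
# the interval proportional to its normal mass
rtrunc_union <- function(n, mean, sd, intervals) {
  mass <- vapply(intervals, function(iv) {
    pnorm(iv[2], mean, sd) - pnorm(iv[1], mean, sd)
  }, numeric(1))
  keep <- mass > 0
  if (!any(keep)) abort("Truncation intervals carry no probability mass.")
  intervals <- intervals[keep]
  mass <- mass[keep]
  pick <- sample.int(length(intervals), n, replace = TRUE, prob = mass)
  out <- numeric(n)
  for (k in seq_along(intervals)) {
    idx <- pick == k
    if (any(idx)) {
      out[idx] <- rtruncnorm(sum(idx), mean, sd, intervals[[k]][1], intervals[[k]][2])
    }
  }
  out
}

#' Generate a synthetic patient cohort
#'
#' Draws `config$n` synthetic patients that all satisfy the eligibility
#' criteria of the configured procedure. Component favourable/unfavourable
#' states are drawn first from the correlated threshold model, then each raw
#' field is drawn from its truncated-normal marginal restricted to the
#' interval implied by the drawn state (an unfavourable age, for instance,
#' comes from `[25, 30) U (60, 70]`). Remission is assigned by the
#' configured mechanism, and follow-up HbA1c / medication fields are drawn
#' consistently with it, so [drs_remission()] on the follow-up columns
#' recovers the `remission` flag. A fixed seed reproduces the cohort
#' exactly; the global RNG state is left untouched.
#'
#' @param config A [drs_generator_config()].
#' @param seed Integer seed; defaults to the seed in `config`, which must
#'   then be set.
#' @return Tibble with one row per patient: `patient_id`, the seven scoring
#'   fields, preoperative `hba1c`, `procedure`, `drs_total` (and subscores),
#'   `remission`, `hba1c_followup`, `on_medication_followup`.
#' @examples
#' cohort <- generate_cohort(drs_generator_config("IISG", n = 5), seed = 1)
#' cohort$drs_total
#' @export
generate_cohort <- function(config, seed = config$seed) {
  if (!inherits(config, "drs_generator_config")) {
    abort("`config` must come from drs_generator_config().")
  }
  if (is.null(seed)) abort("Provide a `seed` (directly or in the config).")

  withr::with_seed(as.integer(seed), {
    n <- config$n
    p <- config$p_unfavourable
    k <- length(p)
    thr <- qnorm(p)

    # correlated unfavourable indicators via a shared latent severity factor
    z <- rnorm(n)
    latent <- sqrt(config$rho) * z +
      sqrt(1 - config$rho) * matrix(rnorm(n * k), n, k)
    unfav <- sweep(latent, 2, thr, "<")
    colnames(unfav) <- names(p)

    m <- config$marginals
    b <- config$bounds
    eps <- 1e-9

    age <- draw_state(unfav[, "age"], n,
      fav = function(nn) rtruncnorm(nn, m$age$mean, m$age$sd, max(30, b$age[1]), min(60, b$age[2])),
      unf = function(nn) rtrunc_union(nn, m$age$mean, m$age$sd,
                                      list(c(b$age[1], 30 - eps), c(60 + eps, b$age[2]))))
    bmi <- draw_state(unfav[, "bmi"], n,
      fav = function(nn) rtruncnorm(nn, m$bmi$mean, m$bmi$sd, 27, b$bmi[2]),
      unf = function(nn) rtruncnorm(nn, m$bmi$mean, m$bmi$sd, b$bmi[1] + eps, 27 - eps))
    duration <- draw_state(unfav[, "duration"], n,
      fav = function(nn) rtruncnorm(nn, m$duration$mean, m$duration$sd, b$duration[1] + eps, 10 - eps),
      unf = function(nn) rtruncnorm(nn, m$duration$mean, m$duration$sd, 10, b$duration[2]))
    cpep <- draw_state(unfav[, "cpeptide"], n,
      fav = function(nn) rtruncnorm(nn, m$cpeptide$mean, m$cpeptide$sd, 4, b$cpeptide[2]),
      unf = function(nn) rtruncnorm(nn, m$cpeptide$mean, m$cpeptide$sd, b$cpeptide[1] + eps, 4 - eps))
    hba1c <- rtruncnorm(n, m$hba1c$mean, m$hba1c$sd, b$hba1c[1] + eps, b$hba1c[2])

    cohort <- tibble::tibble(
      patient_id = sprintf("%s-%03d", config$procedure, seq_len(n)),
      age = age, bmi = bmi, dm_duration = duration,
      microvascular = unname(unfav[, "micro"]),
      macrovascular = unname(unfav[, "macro"]),
      insulin_use = unname(unfav[, "insulin"]),
      c_peptide_stim = cpep,
      hba1c = hba1c,
      procedure = config$procedure
    )
    cohort <- drs_score(cohort)

    prob <- if (config$remission == "band_model") {
      as.numeric(predict_remission(cohort$drs_total, config$procedure,
                                   warn_extrapolation = FALSE))
    } else {
      plogis(config$beta0 + config$beta1 * cohort$drs_total)
    }
    cohort$remission <- rbinom(n, 1, prob) == 1

    fu <- config$followup
    cohort$hba1c_followup <- ifelse(
      cohort$remission,
      rtruncnorm(n, fu$hba1c_remission$mean, fu$hba1c_remission$sd,
                 fu$hba1c_remission$bounds[1], fu$hba1c_remission$bounds[2] - eps),
      rtruncnorm(n, fu$hba1c_no_remission$mean, fu$hba1c_no_remission$sd,
                 fu$hba1c_no_remission$bounds[1], fu$hba1c_no_remission$bounds[2])
    )
    cohort$on_medication_followup <- !cohort$remission
    cohort
  })
}

draw_state <- function(is_unfav, n, fav, unf) {
  out <- numeric(n)
  if (any(!is_unfav)) out[!is_unfav] <- fav(sum(!is_unfav))
  if (any(is_unfav)) out[is_unfav] <- unf(sum(is_unfav))
  out
}
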