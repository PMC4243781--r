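---
title: "Methods: the Diabetes Remission Score, its band model, and cohort reconstruction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the Diabetes Remission Score, its band model, and cohort reconstruction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drscore)
```

## The score

The Diabetes Remission Score (DRS) is a point score for predicting remission
of type 2 diabetes after two metabolic operations: ileal interposition with
sleeve gastrectomy (IISG) and ileal interposition with diverted sleeve
gastrectomy (IIDSG). Seven preoperative variables are each dichotomised into
a favourable state (1 point) or an unfavourable state (2 points), so the
total ranges from 7 to 14, lower being better:

| component | favourable (1) | unfavourable (2) |
|---|---|---|
| age | 30–60 y | < 30 or > 60 y |
| body mass index | ≥ 27 kg/m² | < 27 kg/m² |
| diabetes duration | < 10 y | ≥ 10 y |
| microvascular complications | absent | present |
| macrovascular complications | absent | present |
| preoperative insulin use | no | yes |
| stimulated C-peptide | ≥ 4 ng/mL | < 4 ng/mL |

The components carry equal weight by design; there is no refitting or
recalibration in this package — `drs_score()` encodes the table verbatim.
Deliberate boundary readings: the age window is inclusive at both ends
(because the unfavourable row is strictly "< 30 or > 60"); BMI exactly 27
and C-peptide exactly 4 are favourable; a duration of exactly 10 years is
unfavourable. Thresholds are applied to the raw values with no rounding.
Totals map to severity grades: grade 1 (mild, 7–8), grade 2 (moderate,
9–11), grade 3 (severe, 12–14).

Missing data policy: any missing or non-finite scoring field is a hard
error naming the field. A one-point error is material on an eight-point
scale, so silent imputation is never acceptable here. The vascular
complication flags enter pre-adjudicated; the conventional definitions
(retinopathy/nephropathy/neuropathy for microvascular; coronary,
cerebrovascular or peripheral arterial disease for macrovascular) are
documented but not enforced, and the C-peptide value is accepted as given,
whatever stimulation protocol produced it.

## Eligibility and the remission endpoint

`drs_eligibility()` encodes the derivation study's inclusion rules per
procedure: age 25–70 (inclusive), diabetes duration strictly greater than
1 year (IISG) or 5 years (IIDSG), HbA1c strictly above 7%, BMI ≥ 20 kg/m²
(IISG) or strictly > 18.5 kg/m² (IIDSG), and stimulated C-peptide strictly
above 1.5 ng/mL. Every violated criterion is reported, not just the first.
Exclusion diagnoses (type 1 diabetes, undetectable fasting C-peptide,
recent ketoacidosis, pregnancy, severe comorbidity) and the never-defined
"stable weight" criterion enter only as optional boolean flags.

Remission (`drs_remission()`) is HbA1c strictly below 6.5% without any
glucose-lowering medication — comparable to ADA partial remission. The
inequality is strict: 6.5% exactly is not remission.

## The band model

`drs_outcome_model()` maps a total score and procedure to the remission
probability observed in the derivation cohorts: under IISG every patient at
DRS 7–8 remitted, 35% at DRS 9, and none at DRS ≥ 10; under IIDSG every
patient at DRS 8–10 remitted, 55% at DRS 11, and none at DRS ≥ 12. The
intermediate probabilities are empirical cohort rates, not smoothed model
output, and the package deliberately applies no logistic or isotonic
smoothing; the bands ship in a plain JSON file that users can replace.

Two edges needed decisions. First, the IIDSG no-remission cut-off is
implemented as DRS ≥ 12, the form backed by the per-score remission
statements, although a looser "more than 12" phrasing also appears in the
source's summary; the discrepancy is resolved in favour of the per-score
account. Second, no IIDSG patient with DRS 7 was observed (that cohort's
range was 8–14), so `predict_remission(7, "IIDSG")` returns the band value
1.0 but flags — and by default warns about — the extrapolation rather than
returning it silently.

`recommend_procedure()` encodes the selection guidance: DRS 7–8 → IISG
only; DRS 9–11 → IIDSG; DRS 12–14 → neither studied procedure offers an
expected remission. This coincides with the severity grades, and the
package property-tests that the recommended procedure never has a lower
band probability than the alternative.

## Two-sample tests from printed summaries

Published cohort tables give n, mean and SD but not raw data, so
`drs_t_test()` computes the two-sided unpaired t-test directly from
summaries. Both classical variants are provided: pooled-variance
(df = n₁+n₂−2) and Welch–Satterthwaite. The source describes its analysis
only as an "unpaired t test" without naming a variant; the package defaults
to Welch (the safer assumption under unequal variances) and labels every
result with the variant used. Fed a sample's own summaries, either variant
reproduces `stats::t.test()` on the raw data to machine precision, which the
test suite checks on a thousand random small samples. When both SDs are
zero the statistic is degenerate and the package returns t = 0, p = 1 for
equal means (p = 0 otherwise) by documented convention. Percentages in
reports are rounded half-up to whole percent, matching clinical-table
practice (21/46 prints as 46%). No multiplicity correction is applied —
none was used in the original analysis — and reports state the number of
tests performed.

## The synthetic cohort generator

No patient-level data are deposited for this study, so the generator
emulates cohorts with the published marginal structure, for testing and
simulation only.

**Raw fields.** Age, BMI, duration and HbA1c follow truncated normal
distributions with the published group means and SDs, truncated at the
eligibility bounds — the simplest structure consistent with the printed
marginals. C-peptide has no published distribution; a truncated normal
(mean 3.5 ng/mL IISG, 3.2 IIDSG, SD 1.2, support 1.5–12) was chosen once as
a clinically plausible shape for an insulin-reserve-selected cohort.

**Component states.** Each of the seven components is unfavourable with a
configured probability, and the seven indicators share an exchangeable
latent "severity" factor (a Gaussian copula threshold model with
correlation ρ): comorbid burden clusters in real patients, and independent
components provably cannot reach the published score SDs (seven independent
Bernoulli terms cap the SD at √1.75 ≈ 1.32, below the IISG value of 1.4).
Raw values are then drawn from the marginal restricted to the interval the
state implies — an unfavourable age, for instance, comes from
[25, 30) ∪ (60, 70], staying eligible while scoring 2 — so scores and raw
fields never contradict each other.

**Calibration, done once and frozen.** The unfavourable probabilities were
set from the published tables where possible (truncated-normal tail masses
for age/BMI/duration, the retinopathy fraction for microvascular) and from
clinical priors for the three unmeasured components (macrovascular disease,
insulin use, C-peptide), then rescaled so that their sum equals the
published mean DRS minus 7 (2.2 for IISG, 3.4 for IIDSG) — which makes the
expected cohort mean match the published mean exactly. ρ was then
grid-searched (0 to 0.6 in steps of 0.05, 4000 replicates per point)
to bring the expected per-cohort SD closest to the published value, giving
ρ = 0.15 (IISG) and ρ = 0.05 (IIDSG). These values live in
`inst/extdata/generator_defaults.json` and are not revisited; they are
synthetic emulation parameters, not estimates of the real per-component
prevalences, which the publication does not report.

**Remission.** The default `band_model` mechanism draws each patient's
remission from the band probability at their score, so the published band
rules hold by construction; a `logistic` mechanism
(`plogis(beta0 + beta1 · DRS)`) is provided for parameter-recovery
simulations. Follow-up HbA1c and medication fields are drawn consistently
with the remission flag, so the endpoint classifier recovers the flag
exactly.

**What passing tests do and do not show.** Generated cohorts match the
published score means, pass eligibility by construction, and respect the
band rules — but they assume truncated-normal marginals, an exchangeable
dependence structure, and a single endpoint visit. Real cohorts have
skewed durations, informative missingness, correlated raw fields beyond the
score components, and longitudinal follow-up; none of that is emulated, so
green tests here validate the package's logic, not the score's clinical
performance.

## Reconstruction from printed aggregates

`reconstruct_score_distribution()` treats a results section as a constraint
set over the per-score patient counts: cohort size, mean and SD within a
tolerance (default ±0.05, mirroring one-decimal rounding), observed range
endpoints, the exact remitter total, the band structure of remission, the
printed percentage at the partial score (required to round half-up to the
printed whole percent), and optionally the remitter/non-remitter subgroup
means and SDs. A depth-first search over counts in ascending score order
enumerates *every* solution, pruning on the achievable score sum and sum of
squares and vetting the remitter side as soon as the partial score is
fixed; solutions arrive in lexicographic order, and an empty result is a
proof of infeasibility, not a sampling failure. Because the publication
never states which SD denominator its subgroup tables used, a subgroup SD
matches when either the n−1 or the n form is within tolerance, and each
solution records which form(s) it matched under. Every solution is
re-validated by `check_reconstruction()`, a separate evaluator that expands
counts into raw score vectors and recomputes all statistics directly
(double-entry verification). The search is guarded to n ≤ 200 and a range
width ≤ 8, where exhaustive enumeration completes in seconds.

**A finding: the full printed aggregate sets are infeasible.** With all
constraints active at ±0.05, exhaustive enumeration returns no solution for
either cohort. The obstruction is structural, not a near miss. For IISG,
making 35% of DRS-9 patients remit while keeping the remitter SD at
0.8 ± 0.05 forces at least 13 non-remitting DRS-9 patients, which drives
the non-remitter SD to at least ≈ 1.1 against a printed 0.9. For IIDSG,
a 55% remission fraction at DRS 11 forces at least 5 non-remitting
DRS-11 patients, incompatible with non-remitters summarised as 12.0 ± 0.5
(n = 8). Relaxing all tolerances uniformly, the first feasible points are
±0.10 (IISG) and ±0.15 (IIDSG). Notably, the suspect constraints are the
subgroup moments, whose printed values are duplicated verbatim in the
publication's BMI-stratified table — a plausible typesetting duplication.
The package therefore ships two constraint sets per cohort: the *full* set
(every printed aggregate; provably infeasible at the printed precision,
which the package reports as such) and the *core* set (subgroup moments
dropped; 485 IISG and 17 IIDSG solutions). The remitter total is pinned
exactly in every core solution, so reconstruction-based remission rates
(46% and 72%) do not depend on which solution is chosen.

Printed values that cannot be recomputed from published numbers at all — a
cross-group p-value of 0.1468 whose summaries yield ≈ 0.05 under either
t-test variant, a BMI-subgroup p-value with unprinted group sizes, and the
duplicated BMI-stratified score rows — are listed by `drs_reproduce()`
under `excluded`, with reasons, and are never used as comparison targets.

## Numerical choices and problem sizes

Half-up rounding is implemented as `floor(x + 0.5)` on the scaled value
(base R rounds half to even). Truncated normals are sampled by inverse-CDF
restricted to the truncation interval, exact for these well-conditioned
ranges. The solver's sum-of-squares windows carry a 1e-9 slack against
floating-point edge effects; all count arithmetic is integer. Seeds are
applied with `withr::with_seed()`, so generation never perturbs the
caller's RNG state.

The shipped test suite exercises: all 128 component combinations; 200
random-sample t-test equivalence checks per variant in the unit tests and
1000 in the acceptance suite (tolerance 1e-10); 60 replicate cohorts for
the scaled-down calibration check and 200 in the acceptance suite; and the
four study reconstructions, each of which completes in well under a second.

## Limitations

The package encodes a score derived from a single-centre retrospective
cohort of 75 patients; the derivation study itself cautions that the score
may not transfer to other bariatric or metabolic procedures, and the band
probabilities carry the sampling noise of small per-score cells. The
generator is a testing instrument, not a population model. The
reconstruction solver recovers score *distributions* consistent with the
printed aggregates, not the actual patient data, and when several hundred
solutions exist the data are simply under-determined by what was printed.
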