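{
  "comment": "Printed aggregate statistics of the derivation cohorts, used as reconstruction constraints and as reference values by drs_reproduce(). These are inputs transcribed from the source publication, not package estimates.",
  "IISG": {
    "n": 46,
    "mean": 9.2, "sd": 1.4,
    "score_range": [7, 13],
    "remission_total": 21,
    "remission_pct": 46,
    "full_remission_scores": [7, 8],
    "partial_score": 9, "partial_pct": 35,
    "no_remission_from": 10,
    "remitter": { "mean": 8.1, "sd": 0.8 },
    "nonremitter": { "mean": 10.2, "sd": 0.9 }
  },
  "IIDSG": {
    "n": 29,
    "mean": 10.4, "sd": 1.3,
    "score_range": [8, 14],
    "remission_total": 21,
    "remission_pct": 72,
    "full_remission_scores": [8, 9, 10],
    "partial_score": 11, "partial_pct": 55,
    "no_remission_from": 12,
    "remitter": { "mean": 9.7, "sd": 0.8 },
    "nonremitter": { "mean": 12.0, "sd": 0.5 }
  },
  "between_groups": { "p": 0.0004, "variant": "welch" },
  "within_group_p": "<0.0001",
  "irreproducible": [
    {
      "quantity": "p = 0.1468 (IISG non-remitters 10.2 +/- 0.9, n 25 vs IIDSG remitters 9.7 +/- 0.8, n 21)",
      "reason": "Neither the pooled nor the Welch two-sided t-test on the printed summaries reproduces it; both give approximately 0.05."
    },
    {
      "quantity": "p = 0.07 (IISG BMI >= 35 subgroup, DRS 8.9 +/- 1.7 vs 9.5 +/- 1.1)",
      "reason": "The subgroup sizes are not printed, so no t-test is computable from the published numbers."
    },
    {
      "quantity": "BMI-stratified DRS rows (8.1 +/- 0.8 obese vs 10.2 +/- 0.9 non-obese IISG; 9.7 +/- 0.8 vs 12.0 +/- 0.5 IIDSG)",
      "reason": "They duplicate the remission / non-remission split values exactly; a typesetting duplication cannot be ruled out, so they are not used as targets."
    }
  ]
}
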