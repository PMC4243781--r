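{
  "comment": "Per-procedure remission-probability bands over the DRS total. Probabilities for intermediate scores are the study cohort's empirical rates, not smoothed model output. Edit and pass via drs_outcome_model(path=) to override.",
  "bands": {
    "IISG": [
      { "from": 7, "to": 8, "prob": 1.0 },
      { "from": 9, "to": 9, "prob": 0.35 },
      { "from": 10, "to": 14, "prob": 0.0 }
    ],
    "IIDSG": [
      { "from": 7, "to": 10, "prob": 1.0 },
      { "from": 11, "to": 11, "prob": 0.55 },
      { "from": 12, "to": 14, "prob": 0.0 }
    ]
  },
  "observed_range": {
    "IISG": [7, 13],
    "IIDSG": [8, 14]
  },
  "recommendation": {
    "IISG": [7, 8],
    "IIDSG": [9, 11],
    "neither": [12, 14]
  }
}
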