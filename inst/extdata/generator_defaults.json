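{
  "comment": "Synthetic-cohort generator defaults. Component unfavourable probabilities are a one-time calibration: study-table prevalences (age/BMI/duration tails of the printed truncated-normal marginals, retinopathy counts for microvascular) rescaled so their sum equals the published mean DRS minus 7, with the three unmeasured components (macrovascular, insulin, C-peptide) filled from plausible clinical priors before rescaling. rho is the exchangeable latent-severity correlation, grid-searched once so the expected per-cohort SD of the total matches the published SD. These are synthetic defaults, not estimates of the real cohort.",
  "IISG": {
    "n": 46,
    "p_unfavourable": {
      "age": 0.1903, "bmi": 0.5863, "duration": 0.4097, "micro": 0.3685,
      "macro": 0.1210, "insulin": 0.2419, "cpeptide": 0.2823
    },
    "rho": 0.15,
    "marginals": {
      "age": { "mean": 51.7, "sd": 13.3 },
      "bmi": { "mean": 23.4, "sd": 4.5 },
      "duration": { "mean": 9.9, "sd": 4.8 },
      "hba1c": { "mean": 8.1, "sd": 0.59 },
      "cpeptide": { "mean": 3.5, "sd": 1.2 }
    },
    "bounds": {
      "age": [25, 70], "bmi": [20, 45], "duration": [1, 30],
      "hba1c": [7, 14], "cpeptide": [1.5, 12]
    }
  },
  "IIDSG": {
    "n": 29,
    "p_unfavourable": {
      "age": 0.3137, "bmi": 0.5694, "duration": 0.5703, "micro": 0.4258,
      "macro": 0.1901, "insulin": 0.8079, "cpeptide": 0.5228
    },
    "rho": 0.05,
    "marginals": {
      "age": { "mean": 57.6, "sd": 11.5 },
      "bmi": { "mean": 25.6, "sd": 4.5 },
      "duration": { "mean": 10.1, "sd": 5 },
      "hba1c": { "mean": 9.0, "sd": 0.78 },
      "cpeptide": { "mean": 3.2, "sd": 1.2 }
    },
    "bounds": {
      "age": [25, 70], "bmi": [18.5, 45], "duration": [5, 30],
      "hba1c": [7, 14], "cpeptide": [1.5, 12]
    }
  },
  "followup": {
    "hba1c_remission": { "mean": 5.9, "sd": 0.3, "bounds": [4.5, 6.5] },
    "hba1c_no_remission": { "mean": 7.5, "sd": 0.8, "bounds": [6.5, 12] }
  }
}
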