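{
  "description": "Paper-like synthetic cohort: clinician-diagnosed type 1 diabetes (adults and children) by islet autoantibody status plus a type 2 diabetes control group. Group sizes, GRS means/SDs, the antibody-negative mixture composition, adult clinical rates and adult HLA category frequencies follow the published cohort summaries; fields listed under 'illustrative' are not published at group level and were chosen as realistic placeholders.",
  "illustrative": [
    "adult ia2a/znt8a positivity rates",
    "all child clinical rates, child antibody rates, child HLA frequencies",
    "control-group age, BMI and HLA frequencies"
  ],
  "seed": 20101,
  "mode": "score",
  "groups": [
    {
      "label": "adult_abpos",
      "n": 894,
      "grs": { "mean": 0.271, "sd": 0.026 },
      "age": { "min": 18, "max": 75, "mean": 32, "sd": 11 },
      "clinical": {
        "male": 0.59, "bmi_mean": 24, "bmi_sd": 5,
        "dka": 0.42, "weight_loss": 0.86, "polyuria_polydipsia": 0.94,
        "hospitalised": 0.63, "other_autoimmune": 0.10, "parent_diabetes": 0.19
      },
      "antibodies": {
        "status": "positive",
        "rates": { "gada": 0.90, "ia2a": 0.55, "znt8a": 0.45 }
      },
      "hla": {
        "DR3_DR4_het": 0.19, "DR15_carrier": 0.03,
        "DR3_or_DR4_no_DR15": 0.62, "neutral_XX": 0.16
      }
    },
    {
      "label": "adult_abneg",
      "n": 218,
      "mixture": {
        "weight_t1d": 0.3256880733944954,
        "t1d": { "mean": 0.271, "sd": 0.026 },
        "ctrl": { "mean": 0.229, "sd": 0.034 }
      },
      "age": { "min": 18, "max": 75, "mean": 38, "sd": 12 },
      "clinical": {
        "male": 0.75, "bmi_mean": 27, "bmi_sd": 7,
        "dka": 0.38, "weight_loss": 0.85, "polyuria_polydipsia": 0.91,
        "hospitalised": 0.60, "other_autoimmune": 0.02, "parent_diabetes": 0.33
      },
      "antibodies": { "status": "negative" },
      "hla": {
        "DR3_DR4_het": 0.06, "DR15_carrier": 0.15,
        "DR3_or_DR4_no_DR15": 0.42, "neutral_XX": 0.37
      }
    },
    {
      "label": "child_abpos",
      "n": 642,
      "grs": { "mean": 0.277, "sd": 0.026 },
      "age": { "min": 4, "max": 17.99, "mean": 10, "sd": 3.5 },
      "clinical": {
        "male": 0.52, "bmi_mean": 21, "bmi_sd": 4,
        "dka": 0.45, "weight_loss": 0.80, "polyuria_polydipsia": 0.95,
        "hospitalised": 0.85, "other_autoimmune": 0.03, "parent_diabetes": 0.10
      },
      "antibodies": {
        "status": "positive",
        "rates": { "gada": 0.80, "ia2a": 0.75, "znt8a": 0.65 }
      },
      "hla": {
        "DR3_DR4_het": 0.22, "DR15_carrier": 0.02,
        "DR3_or_DR4_no_DR15": 0.60, "neutral_XX": 0.16
      }
    },
    {
      "label": "child_abneg",
      "n": 60,
      "grs": { "mean": 0.274, "sd": 0.034 },
      "age": { "min": 4, "max": 17.99, "mean": 10, "sd": 3.5 },
      "clinical": {
        "male": 0.55, "bmi_mean": 21, "bmi_sd": 4,
        "dka": 0.42, "weight_loss": 0.78, "polyuria_polydipsia": 0.94,
        "hospitalised": 0.84, "other_autoimmune": 0.04, "parent_diabetes": 0.12
      },
      "antibodies": { "status": "negative" },
      "hla": {
        "DR3_DR4_het": 0.18, "DR15_carrier": 0.04,
        "DR3_or_DR4_no_DR15": 0.58, "neutral_XX": 0.20
      }
    },
    {
      "label": "t2d_control",
      "n": 1924,
      "grs": { "mean": 0.229, "sd": 0.034 },
      "non_autoimmune": true,
      "age": { "min": 30, "max": 80, "mean": 55, "sd": 10 },
      "clinical": {
        "male": 0.55, "bmi_mean": 30, "bmi_sd": 5,
        "dka": 0.01, "weight_loss": 0.20, "polyuria_polydipsia": 0.40,
        "hospitalised": 0.05, "other_autoimmune": 0.04, "parent_diabetes": 0.40
      },
      "antibodies": { "status": "unmeasured" },
      "hla": {
        "DR3_DR4_het": 0.03, "DR15_carrier": 0.25,
        "DR3_or_DR4_no_DR15": 0.40, "neutral_XX": 0.32
      }
    }
  ]
}
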