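{
  "version": 1,
  "description": "Fitted coded-factor response-surface models of the ointment case study. Continuous terms are coded as (x - center)/half-range; the 'method' term is -1 for level A and +1 for level B, so its coefficient is the level-B match value.",
  "factor_space": "ointment",
  "models": [
    {
      "response": "high_shear_visc",
      "units": "Pa.s",
      "intercept": 5.76,
      "terms": [
        {"term": "drug_ratio", "coef": 2.47},
        {"term": "mixing_speed", "coef": 0.30},
        {"term": "petroleum", "coef": -0.21},
        {"term": "liquid_paraffin", "coef": -0.61},
        {"term": "method", "coef": 0.50},
        {"term": "drug_ratio^2", "coef": 1.69},
        {"term": "mixing_speed:liquid_paraffin", "coef": -0.78},
        {"term": "drug_ratio:method", "coef": 0.34},
        {"term": "petroleum:method", "coef": -0.29}
      ],
      "r_squared": 0.99473,
      "p_value": 0.0003
    },
    {
      "response": "low_shear_visc",
      "units": "Pa.s",
      "intercept": 17855.51,
      "terms": [
        {"term": "drug_ratio", "coef": 5993.11},
        {"term": "mixing_time", "coef": -326.77},
        {"term": "mixing_speed", "coef": -1507.23},
        {"term": "petroleum", "coef": -998.91},
        {"term": "liquid_paraffin", "coef": -1710.11},
        {"term": "method", "coef": 1809.43},
        {"term": "mixing_time:mixing_speed", "coef": -1083.93},
        {"term": "mixing_time:liquid_paraffin", "coef": -6274.29},
        {"term": "mixing_speed:method", "coef": 1668.13}
      ],
      "r_squared": 0.95905,
      "p_value": 0.0188
    },
    {
      "response": "storage_modulus",
      "units": "Pa",
      "intercept": 550.40,
      "terms": [
        {"term": "drug_ratio", "coef": 1307.12},
        {"term": "mixing_time", "coef": -283.03},
        {"term": "mixing_speed", "coef": 104.60},
        {"term": "petroleum", "coef": -125.86},
        {"term": "liquid_paraffin", "coef": -211.11},
        {"term": "method", "coef": 338.31},
        {"term": "drug_ratio^2", "coef": 942.47},
        {"term": "drug_ratio:method", "coef": 563.69},
        {"term": "mixing_time:method", "coef": -215.64}
      ],
      "r_squared": 0.98888,
      "p_value": 0.0015
    },
    {
      "response": "yield_stress",
      "units": "Pa",
      "intercept": 42.00,
      "terms": [
        {"term": "mixing_time", "coef": 2.23},
        {"term": "mixing_speed", "coef": -3.39},
        {"term": "petroleum", "coef": 8.83},
        {"term": "liquid_paraffin", "coef": -6.96},
        {"term": "method", "coef": 2.33},
        {"term": "mixing_speed^2", "coef": 10.86},
        {"term": "mixing_time:liquid_paraffin", "coef": -5.04},
        {"term": "petroleum:liquid_paraffin", "coef": -7.37}
      ],
      "r_squared": 0.913938,
      "p_value": 0.0260
    }
  ]
}
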