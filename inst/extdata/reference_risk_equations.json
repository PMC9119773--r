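{
  "ANN-RS": {
    "label": "ANN-RS",
    "intercept": -5.659,
    "confounder_coef": 0.107,
    "pi_coef": 0.160
  },
  "SVM-RS": {
    "label": "SVM-RS",
    "intercept": -6.131,
    "confounder_coef": 0.415,
    "pi_coef": 0.174
  }
}
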