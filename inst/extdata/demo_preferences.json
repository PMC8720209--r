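{
  "thresholds": {
    "erectile_function": "50%",
    "urinary_incontinence": "about once a week",
    "nocturia": "2",
    "bowel_incontinence": "rarely or never"
  },
  "wta_side_effect": {
    "erectile_function": 20000,
    "urinary_incontinence": 15000,
    "nocturia": 2000,
    "bowel_incontinence": 30000
  },
  "wta_alternative_burden": {
    "active_surveillance": 5000,
    "SBRT": 500,
    "EBRT_standard": 3000,
    "EBRT_hypofractionated": 1500
  },
  "wta_failure": 50000
}
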