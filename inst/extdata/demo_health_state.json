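{
  "erectile_function": "100%",
  "urinary_incontinence": "rarely or never",
  "nocturia": "2",
  "bowel_incontinence": "rarely or never"
}
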