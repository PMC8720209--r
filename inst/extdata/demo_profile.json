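{
  "t_stage": "cT1c",
  "grade_group": 1,
  "psa": 6.2,
  "cores_positive": 2,
  "cores_total": 12,
  "max_single_core_involvement": 40,
  "cores_with_grade_group_4_or_5": 0
}
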