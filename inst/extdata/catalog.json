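{
  "treatments": ["active_surveillance", "SBRT", "EBRT_standard", "EBRT_hypofractionated", "EBRT_HDR", "EBRT_ADT", "EBRT_HDR_ADT"],
  "eligibility": {
    "LOW": ["active_surveillance", "SBRT", "EBRT_standard", "EBRT_hypofractionated"],
    "INTERMEDIATE": ["SBRT", "EBRT_standard", "EBRT_hypofractionated", "EBRT_HDR", "EBRT_ADT"],
    "HIGH": ["EBRT_ADT", "EBRT_HDR_ADT"]
  },
  "success": [
    {
      "treatment_id": "active_surveillance",
      "risk_broad": "LOW",
      "p_ffbf": 0.92
    },
    {
      "treatment_id": "SBRT",
      "risk_broad": "LOW",
      "p_ffbf": 0.95
    },
    {
      "treatment_id": "EBRT_standard",
      "risk_broad": "LOW",
      "p_ffbf": 0.93
    },
    {
      "treatment_id": "EBRT_hypofractionated",
      "risk_broad": "LOW",
      "p_ffbf": 0.93
    },
    {
      "treatment_id": "SBRT",
      "risk_broad": "INTERMEDIATE",
      "p_ffbf": 0.9
    },
    {
      "treatment_id": "EBRT_standard",
      "risk_broad": "INTERMEDIATE",
      "p_ffbf": 0.88
    },
    {
      "treatment_id": "EBRT_hypofractionated",
      "risk_broad": "INTERMEDIATE",
      "p_ffbf": 0.88
    },
    {
      "treatment_id": "EBRT_HDR",
      "risk_broad": "INTERMEDIATE",
      "p_ffbf": 0.92
    },
    {
      "treatment_id": "EBRT_ADT",
      "risk_broad": "INTERMEDIATE",
      "p_ffbf": 0.9
    },
    {
      "treatment_id": "EBRT_ADT",
      "risk_broad": "HIGH",
      "p_ffbf": 0.8
    },
    {
      "treatment_id": "EBRT_HDR_ADT",
      "risk_broad": "HIGH",
      "p_ffbf": 0.85
    }
  ],
  "note": "Success probabilities (5-year FFBF) are illustrative placeholders, not trial estimates; supply institution-specific values in production."
}
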