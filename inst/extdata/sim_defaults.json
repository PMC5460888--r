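{
  "targeting_efficiency": 0.001,
  "n_cells_selected": 1500000,
  "loh_survivor_rate": 0.00165882352941176,
  "background_survivor_rate": 0.000105882352941176,
  "n_colonies_picked": 18,
  "calibration_targets": {
    "nonloh_fraction_abrogating": 0.4,
    "nonloh_fraction_neutral": 0.06
  }
}
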