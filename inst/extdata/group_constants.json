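{
  "bangladesh": {"M5": 0.382, "U3": 1.22, "weight_kg": 8.4, "retinol_umol_l": 0.785, "dose_umol": 1.17},
  "philippines": {"M5": 0.462, "U3": 2.56, "weight_kg": 8.8, "retinol_umol_l": 1.02, "dose_umol": 1.17},
  "guatemala": {"M5": 0.848, "U3": 2.83, "weight_kg": 15, "retinol_umol_l": 1.24, "dose_umol": 1.17}
}
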