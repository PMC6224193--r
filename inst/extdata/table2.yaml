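# Monte-Carlo sweep ranges (uniform, independent draws per network).
sweep_ranges:
  j_nS: [0.1, 0.4]
  g_rc: [7, 10]
  R_lgn_hz: [5, 15]
  R_bkg_hz: [5, 15]
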