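# Full-size layer 4 network model: neuron, architecture and input parameters.
# Key names carry unit suffixes; symbols follow the model parameter table.
neuron:
  C_pF: 200
  gL_nS: 10
  VL_mV: -70
  Vexc_mV: 0
  Vinh_mV: -85
  Vtheta_mV: -50
  Vreset_mV: -70    # decision parameter (reset to rest)
  t_ref_ms: 2       # decision parameter
  tau_syn_ms: 5
network:
  "N": 5000
  NE: 4000
  NI: 1000
  in_degree_e: 400
  in_degree_i: 100
  j_nS: 0.3         # excitatory peak conductance; inhibitory is g_rc * j = 2.4 nS
  g_rc: 8
  delay_ms: 1       # decision parameter
input:
  js_nS: 0.5
  g_fw: 1.25        # g_fw * js = 0.625 nS thalamic weight onto inhibition
  n_lgn: 100
  R_lgn_hz: 8
  n_bkg: 100
  R_bkg_hz: 14.2
factors:
  delta_e: 0.9
  delta_i: 0.6
  pi_fb: 1.5
simulation:
  duration_ms: 9000
  dt_ms: 0.1
  transient_discard_ms: 500
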