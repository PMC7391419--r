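name: pps-default
grid:
  'n': 41
  tactile_spacing: 0.5
  tactile_extent: 20.0
  visual_spacing: 10.0
  visual_extent: 400.0
neurons:
  tau_ms:
    t: 20.0
    v: 20.0
    m: 20.0
  f_min:
    t: 0.0
    v: 0.0
    m: 0.0
  f_max:
    t: 1.0
    v: 1.0
    m: 1.0
  theta:
    t: 12.0
    v: 12.0
    m: 12.0
  r:
    t: 1.2
    v: 1.2
    m: 0.35
lateral:
  exc_amp: 0.15
  exc_sigma: 1.0
  inh_amp: 0.05
  inh_sigma: 4.0
feedforward:
  w0_t: 2.0
  w0_v: 20.0
  lambda_v: 60.0
feedback:
  b_t: 6.0
  b_v: 2.0
hebb:
  rho0_t: 0.001125
  rho0_v: 0.001125
  gate_theta: 0.05
  tau_h_s: 4.0
  update_dt_ms: 1.0
stimulus:
  tact_amp: 20.0
  tact_sigma: 1.0
  tact_dur_ms: 50.0
  vis_amp: 30.0
  vis_sigma: 6.0
  start_distance: 200.0
  velocity: 75.0
sim:
  dt_ms: 1.0
  horizon_ms: 500.0
  iti_ms: 2000.0
  p_th: 4.0
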