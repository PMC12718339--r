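frame_interval: 0.5
rounds: 30
aps_per_round: 50.0
ap_frequency: 10.0
inter_round_interval: 60.0
rounds_start: 360.0
reference_round_start: 20.0
glucose_timeline:
- start_s: 0.0
  glucose_mM: 5.0
- start_s: 60.0
  glucose_mM: 0.0
nh4cl_epoch:
  start_s: 2145.0
  end_s: 2175.0
long_train: ~
span_s: 2185.0
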