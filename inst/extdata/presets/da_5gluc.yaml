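glycogen_store_0: 1.0
gp_activity: 1.0
gp_rate: 0.0175
glucose_uptake_gain: 0.004
atp_rest_cost: 0.007
atp_cost_per_ap: 0.0005
recycle_cost: 0.35
endocytosis_tau: 8.0
atp_capacity_halfpoint: 0.7
hill_n: 6.0
exo_pool_fraction_per_round: 0.15
consumption_knee: 0.5
glycogen_per_atp: 0.032
neuron_cv: 0.5
noise_sd: 0.05
bleach_rate: 2.0e-05
sensor_kd: 3.0
d2r_tone: 1.0
glucose_mM: 5.0
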