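type: fd
task: high
background_khz: 22
prepulse_khz: [14.96, 18.48, 19.80, 20.24, 20.68, 21.12, 21.56, 21.78, 22]
background_level_db: 70
startle_level_db: 120
startle_dur_ms: 20
prepulse_dur_ms: 80
ramp_ms: 1
n_lead_sa: 9
n_prepulse_trials: 120
n_tail_sa: 1
iti_s: [10, 20]
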