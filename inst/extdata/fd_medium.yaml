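type: fd
task: medium
background_khz: 12
prepulse_khz: [15.84, 13.84, 13.20, 12.96, 12.72, 12.48, 12.24, 12.12, 12]
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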