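type: gap
n_sa_per_band: 8
n_ga_per_band: 8
background_level_db: 60
startle_level_db: 115
startle_dur_ms: 50
gap_dur_ms: 40
gap_lead_ms: 100
pre_startle_background_s: [10, 20]
post_startle_background_ms: 500
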