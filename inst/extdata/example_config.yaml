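# Toy simulation configuration (keys = sim_config() field names).
n_participants: 4
n_trials_per_session: 8
trial_duration: 3.0
sampling_rate: 500
base_rate_mean: 1.4
base_rate_sd: 0.45
post_rate_multiplier: 0.85
seed: 42
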