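# Example pipeline configuration: simulate a small cohort and run every
# stage at desk scale.
seed: 7
out_dir: nbdc_run
simulate:
  n_participants: 20
  followup_days: 84
  seed: 7
settings:
  min_hours: 12
  min_valid_days: 10
  window_days: 14
  cutoff_date: 2020-02-01
entropy:
  m: 2
  r_fraction: 0.2
  max_scale: 24
sampler:
  draws: 300
  warmup: 300
  chains: 2
  seed: 7
predict_schemes: [lao]
predict_models: [full, baseline]
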