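seed: 1.0
simulation:
  n_samples: 60.0
  n_chromosomes: 10.0
  genes_per_arm: 100.0
  probes_per_arm: 20.0
  sigma_arm: 1.0
  probe_noise: 0.3
  expr_noise: 1.0
thresholds:
  screen_r: 0.5
  alpha_coherence: 0.05
  alpha_cox: 0.05
  alpha_logrank: 0.1
  min_module_size: 5.0
validation:
  n_background: 1000.0
  n_adjust: 1000.0
  pair_cap: 50000.0
  required_cohorts: ~
  split: global_mean
fdr:
  n_perm: 100.0
  n_runs: 200.0
  n_adjust: 200.0
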