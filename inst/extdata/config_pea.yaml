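# Pea study configuration: 4 daily temperatures + 3 daily water amounts,
# 100 seeds per run, 3 concurrent chambers.
parameters:
  - {name: t1, unit: degC, low: 0, high: 40, scaled_high: 1.0, eps_exploit: 0.1, eps_explore: 10, precision: 0.1}
  - {name: t2, unit: degC, low: 0, high: 40, scaled_high: 1.0, eps_exploit: 0.1, eps_explore: 10, precision: 0.1}
  - {name: t3, unit: degC, low: 0, high: 40, scaled_high: 1.0, eps_exploit: 0.1, eps_explore: 10, precision: 0.1}
  - {name: t4, unit: degC, low: 0, high: 40, scaled_high: 1.0, eps_exploit: 0.1, eps_explore: 10, precision: 0.1}
  - {name: w1, unit: ml, low: 0, high: 250, scaled_high: 0.5, eps_exploit: 1, eps_explore: 100, precision: 1}
  - {name: w2, unit: ml, low: 0, high: 250, scaled_high: 0.5, eps_exploit: 1, eps_explore: 100, precision: 1}
  - {name: w3, unit: ml, low: 0, high: 250, scaled_high: 0.5, eps_exploit: 1, eps_explore: 100, precision: 1}
seeds_per_trial: 100
batch_size: 3
kappa: auto
explore_subset_rule: exclude_init
noise_mode: global
n_restarts: 30
seed: 1
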