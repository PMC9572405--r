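# Standard study conditions: 2.55 kbp worm-like chain in a helical channel
# at D/P = 0.5 (all quantities in reduced units; sigma = 2.5 nm).
"N": 300
k_s: 80.0
r0: 1.0
k_b: 20.0
bend_convention: half
P: 20.0
gamma: 1.0
dt: 0.01
seed: 1
channel:
  D: 10.0
  R_H_fraction: 0.3333333333333333
  omega: 1
protocol:
  pre_equilibration_steps: 400000
  production_steps: 800000
  sample_interval: 2000
  force: 0.0
  n_repeats: 1
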