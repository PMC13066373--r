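# Face-to-face contact network with the conference-fit Pareto parameters.
# Times are data ticks.
model: tn
seed: 1
t_end: 7249
params:
  n_nodes: 274
  alpha_a: 0.76
  lambda_a: 0.4
  alpha_end: 1.4
  lambda_end: 0.61
  w: 1
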