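# Germinal-center affinity maturation.  t_end is in hours (50 days);
# rates are per hour.
model: bcell
seed: 1
t_end: 1200
params:
  n_b: 1000
  n_t: 10
  lambda_bt: 0.146
  lambda_unbind: 2
  lambda_apop: 0.084
  lambda_div: 0.134
  beta: 10
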