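# Hes1 delayed negative feedback, energy-unconstrained elongation.
# Times are minutes.
model: hes1
seed: 1
t_end: 2000
params:
  beta: 100
  gamma: 0
  hill_h: 4.1
  lambda_trans: 0.01
  lambda_degM: 0.029
  lambda_degP: 0.031
  tau0: 20
  alpha_elong: 3
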