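# Desk-scale wild-type toy protocol (tested path)
preset = toy-wt
n_tf = 20
alpha_off = 1e-5
alpha_on = 1e-5
attempt_interval = 100
eps_strong = 8
eps_weak = 3
t_pushoff = 100
t_equil = 400
t_prod = 2500
sample_interval = 100
n_runs = 10
base_seed = 100
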