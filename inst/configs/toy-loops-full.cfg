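# Full-scale looped-chain protocol (eight permanent loops)
preset = toy-loops
n_tf = 20
alpha_off = 1e-5
alpha_on = 1e-5
attempt_interval = 100
eps_strong = 8
eps_weak = 3
t_pushoff = 1000
t_equil = 10000
t_prod = 100000
sample_interval = 100
n_runs = 800
base_seed = 1
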