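# Dense ODE-cascade trajectory export (thin with subsample_trajectory()).
output_dir: out/ode_sim
seed: 1
simulator: ode
n_dense: 2000
t_max: 10
stimulus: 1
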