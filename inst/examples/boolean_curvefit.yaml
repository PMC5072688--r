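# Four-family curve comparison on cell-death-vs-input trajectories from
# the ensemble Boolean simulator of the 7-node cell-death network.
output_dir: out/boolean_curvefit
seed: 1
n_steps: 100
x_column: EGFR
y_column: CellDeath
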