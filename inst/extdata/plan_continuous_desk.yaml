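# Desk-scale continuous-x effect study: all six ICC levels,
# 100 shift SDs x 5 replicates = 500 accepted samples per level.
x_type: continuous
icc_levels: ['0.001', '0.003', '0.01', '0.03', '0.1', '0.3']
n_shift_values: 100
replicates_per_shift: 5
beta1_true: 1
master_seed: 20260901
scale_factor: 1
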