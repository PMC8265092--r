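# Binary-x stress corner: target prevalence 0.05 at ICC level 0.3,
# 1000 accepted samples, null slope (Type I study).
x_type: binary
icc_levels: ['0.3']
target_prevalences: [0.05]
n_shift_values: 100
replicates_per_shift: 10
beta1_true: 0
master_seed: 20260906
scale_factor: 1
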