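n_templates: 500
n_clones: 1
pcr1_cycles: 5
priming_prob: 0.9
loop_reamp_prob: 0.005
pcr2_cycles: 20
efficiency_shape1: 2.0
efficiency_shape2: 2.0
efficiency_range:
- 0.6
- 1.0
seq_error_rate: 0.005
read_length: 170
sequencing_depth: 6000
umi_length: 8
synthetic_umi_length: 8
shm_rate: 0.0
qual_pass_fraction: 0.95
seed: 1
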