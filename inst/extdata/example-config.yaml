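# Example pipeline configuration. Unspecified keys take package defaults
# (validate_config() rejects unknown keys and out-of-range values).
n_subjects: 7
runs_choices: [4, 5, 6]
n_voxels: 175
t_preselect: 1.53
tsnr_sd_mult: 2
t_percentile: 90
window: [3, 7]
svm_cost: 1
gg_threshold: 0.75
seed: 1
coupling:
  - source_area: A3A
    source_layer: superficial
    target_area: A7
    target_layer: middle
    stereo: correlated
    rho: 0.5
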