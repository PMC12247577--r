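# Example configuration for run_battery_config() /
# inst/scripts/scenario_battery.R. Reduced settings for a quick run;
# raise n_reps/n_perm (100 / 1000) for full-fidelity analyses.
seed: 1
n_subjects: 4
n_trials: 720
scenarios:
  - rotated_only
  - unique_scheme_both
  - unique_scheme_one
n_reps: 5
null_reps: 1
n_perm: 99
decode_reps: 5
include_rotation_signal: false
amplitude: 1
output_dir: battery_out
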