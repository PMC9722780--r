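# Default display profile: two 16-bar dynamic 1-D Gaussian noise fields at
# 30 Hz for 4500 ms, ramping central target, probabilistic 100-ms cue.
n_bars_per_field: 16
bar_width_deg: 0.29
field_size_deg: 4.6
frame_rate_hz: 30
duration_ms: 4500
noise_sd: 0.1
target_ramp_slope: 0.05
target_ramp_offset: -3
target_onset_range_ms: [0, 500]
cue_probability: 0.94
cue_validity: 0.75
cue_onset_range_ms: [500, 2000]
cue_duration_ms: 100
pixel_size_deg: 0.018
clip_range: [-1, 1]
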