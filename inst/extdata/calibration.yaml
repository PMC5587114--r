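# Calibration constants for the baseplate digital twin (versioned).
# field_scale / read_threshold / shielding_gain / coupling_noise_sd and the
# per-site tag geometry are fitted once so that simulated 24 h read rates
# reproduce the measured per-site values and their ordering.  Site heights
# are effective coupling distances absorbing orientation scatter and tissue
# attenuation, not anatomical measurements.
version: "1.0"
field_scale: 900
read_threshold: 1.0
shielding_gain: 4.0
coupling_noise_sd: 0.6
sites:
  ventral_midline:
    height: 2.5
    axis: body
    lateral_offset: 0
  flank_vertical:
    height: 3.4
    axis: vertical
    lateral_offset: 2
  flank_horizontal:
    height: 8.75
    axis: body
    lateral_offset: 2
  interscapular:
    height: 10.15
    axis: body
    lateral_offset: 0
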