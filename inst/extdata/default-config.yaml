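gradient_inplane_T_per_m: 1.13
gradient_axial_T_per_m: 0.85
drive_frequency_Hz: 26315.789473684209952
drive_amplitude_mT: 5.8
sample_rate_per_s: 1000000.0
periods_per_readout: 35.0
readouts_per_projection: 132.0
projections_per_image: 27.0
shift_frequency_Hz: 2.7
shift_field_peak_mT: 102.264999999999986
gantry_rpm: 6.0
image_sweep_degrees: 180.0
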