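# EuXFEL burst-mode timing, early user operation
name: euxfel
train_period_s: 0.1
pulses_per_train: 32
intra_spacing_ns: 889
calibration_pulses: 2
record_stride: 2
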