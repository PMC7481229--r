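label,minutes,volume_ul,hits
continuous,26,260,577
segmented_subset,26,110,735
segmented_all,134,962,5770
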