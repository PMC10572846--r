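subject,peak_rise_percent,fmri_peak_t
1,87.9,27.6
2,67.7,18.3
3,71.7,23.8
4,46.6,15.2
5,36.3,23.4
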