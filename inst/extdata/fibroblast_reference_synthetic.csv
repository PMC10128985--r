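time_h,fibroblasts
0,21
48,39
168,67
672,36
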