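1 1 1.000000000000
50 50 1.000000000000
50 30 0.216188354811
50 70 0.215809587875
31 51 0.215809587875
11 91 1.000000000000
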