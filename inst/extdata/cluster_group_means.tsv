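group_min	mean_um	sd_um
0	0.597	0.514
5	0.483	0.395
10	0.465	0.402
20	0.495	0.433
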