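snp_a	snp_b	r2
rsx0001	rsx0002	0.15
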