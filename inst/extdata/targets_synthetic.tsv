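name	protospacer	pam	pam_side	seed_len	gc_percent
PS4_synthetic	GGTGATCCAGGCACTTAAGC	TGG	3prime	10	55
EMX1_synthetic	GCCGGCGCAGTCGGGCACAC	CGG	3prime	10	80
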