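chrom	start	end	arm
chr7	0	1200000	p
chr7	1200000	2400000	q
chr10	0	1200000	p
chr10	1200000	2400000	q
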