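pathway	gene	role
RTK_PI3K_MTOR	EGFR	upstream
RTK_PI3K_MTOR	MET	upstream
RTK_PI3K_MTOR	PDGFRA	upstream
RTK_PI3K_MTOR	KIT	upstream
RTK_PI3K_MTOR	KDR	upstream
RTK_PI3K_MTOR	PIK3CA	downstream
RTK_PI3K_MTOR	PIK3R1	downstream
RTK_PI3K_MTOR	PTEN	downstream
RTK_PI3K_MTOR	AKT1	downstream
RTK_PI3K_MTOR	TSC2	downstream
RTK_PI3K_MTOR	RPTOR	downstream
RTK_PI3K_MTOR	MTOR	downstream
RB_CELL_CYCLE	CDK4	parallel_arm
RB_CELL_CYCLE	CDK6	parallel_arm
RB_CELL_CYCLE	CDKN2A	parallel_arm
RB_CELL_CYCLE	RB1	downstream
P53_AXIS	MDM2	upstream
P53_AXIS	TP53	downstream
RAS_MAPK	NF1	upstream
RAS_MAPK	BRAF	downstream
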