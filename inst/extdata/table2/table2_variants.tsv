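sample	gene	alteration_class	variant_spec	consequence	focality
GBM1	PIK3R1	snv	R562del	inframe_indel	.
GBM1	MET	snv	R755fs	frameshift	.
GBM1	MET	gain	gain	.	focal
GBM3	PIK3CA	snv	V344G	missense	.
GBM4	EGFR	gain	gain	.	.
GBM4	PTEN	snv	W111C	missense	.
GBM4	PTEN	loss	loss	.	arm_level
GBM5	PDGFRA	gain	gain	.	.
GBM5	KIT	gain	gain	.	.
GBM5	KDR	gain	gain	.	.
GBM6	PIK3CA	snv	G542K	missense	.
GBM6	PTEN	snv	N59fs	frameshift	.
GBM6	EGFR	gain	gain	.	arm_level
GBM7	SMO	snv	R421*	nonsense	.
GBM7	NF1	snv	Q270*	nonsense	.
GBM8	POLE	snv	P1505S	missense	.
GBM8	MSH2	snv	c.366+1G>A	splice_site	.
GBM8	.	burden	High mutation burden	.	.
GBM9	EGFR	gain	gain	.	.
GBM9	KDR	snv	R1022*	nonsense	.
GBM9	PIK3R1	snv	E443del	inframe_indel	.
GBM10	MGMT	loss	loss	.	.
GBM10	PTEN	snv	R130*	nonsense	.
GBM10	PTEN	loss	loss	.	arm_level
GBM10	NF1	snv	E1722*	nonsense	.
GBM12	EGFR	snv	A289V	missense	.
GBM12	EGFR	gain	gain	.	focal
GBM12	PIK3R1	snv	D560G	missense	.
GBM13	MDM2	gain	gain	.	focal
GBM13	CDK4	gain	gain	.	focal
GBM13	PTEN	snv	R47S	missense	.
GBM14	EGFR	snv	A289V	missense	.
GBM14	EGFR	gain	gain	.	focal
GBM14	PIK3R1	snv	W597G	missense	.
GBM14	PTEN	loss	loss	.	arm_level
GBM15	PIK3R1	snv	T473P	missense	.
GBM15	EGFR	gain	gain	.	arm_level
GBM15	CDKN2A	loss	loss	.	focal
GBM15	PTEN	loss	loss	.	arm_level
GBM16	PTEN	snv	Y16*	nonsense	.
GBM16	EGFR	gain	gain	.	focal
GBM16	PDGFRA	gain	gain	.	focal
GBM17	BRAF	snv	V600E	missense	.
GBM17	EGFR	gain	gain	.	.
GBM21	EGFR	snv	R222C	missense	.
GBM21	EGFR	gain	gain	.	focal
GBM21	MET	snv	P791L	missense	.
GBM21	MET	gain	gain	.	focal
GBM21	PTEN	loss	loss	.	arm_level
GBM21	CDKN2A	loss	loss	.	focal
GBM22	PTEN	snv	V119F	missense	.
GBM22	PTEN	loss	loss	.	arm_level
GBM22	STAG2	loss	loss	.	focal
GBM22	NF1	snv	283fs	frameshift	.
GBM22	NF1	loss	loss	.	focal
GBM22	TP53	snv	R158H	missense	.
GBM23	IDH1	snv	R132H	missense	.
GBM23	RPTOR	snv	A578G	missense	.
GBM24	PIK3CA	snv	R93W	missense	.
GBM24	EGFR	gain	gain	.	arm_level
GBM24	MET	gain	gain	.	focal
GBM24	PTEN	snv	R335*	nonsense	.
GBM24	PTEN	snv	T277I	missense	.
GBM24	PTEN	loss	loss	.	arm_level
GBM24	CDKN2A	loss	loss	.	focal
GBM24	PALB2	loss	loss	.	arm_level
GBM25	POLA1	snv	G1178	missense	.
GBM25	MSH2	snv	c.366+1G>A	splice_site	.
GBM25	TP53	snv	R175H	missense	.
GBM25	TP53	snv	G245S	missense	.
GBM25	PDGFRA	snv	Y375H	missense	.
GBM25	PDGFRA	gain	gain	.	focal
GBM25	KIT	gain	gain	.	focal
GBM25	KDR	gain	gain	.	focal
GBM25	.	burden	High mutation burden	.	.
GBM26	PIK3CA	snv	R88Q	missense	.
GBM26	MDM2	gain	gain	.	focal
GBM26	CDK4	gain	gain	.	focal
GBM26	PTEN	loss	loss	.	arm_level
GBM27	EGFR	sv	VIII	.	.
GBM27	EGFR	gain	gain	.	focal
GBM27	CDKN2A	loss	loss	.	focal
GBM27	PTEN	loss	loss	.	arm_level
GBM28	PIK3R1	snv	Q579fs	frameshift	.
GBM28	PIK3CA	snv	D939G	missense	.
GBM28	MET	gain	gain	.	focal
GBM28	PDGFRA	gain	gain	.	focal
GBM28	CDKN2A	loss	loss	.	focal
GBM28	PTEN	loss	loss	.	arm_level
GBM29	EGFR	snv	A289V	missense	.
GBM29	EGFR	gain	gain	.	focal
GBM29	PTEN	snv	R130*	nonsense	.
GBM29	PTEN	loss	loss	.	arm_level
GBM29	CDKN2A	loss	loss	.	focal
GBM29	CDK4	gain	gain	.	focal
GBM31	IDH1	snv	R132H	missense	.
GBM31	TSC2	snv	P1215fs	frameshift	.
GBM31	TP53	snv	R175H	missense	.
GBM31	CDKN2A	loss	loss	.	focal
GBM32	PIK3R1	snv	A483P	missense	.
GBM32	STAG2	loss	loss	.	focal
GBM32	PTEN	snv	M198R	missense	.
GBM32	PTEN	loss	loss	.	arm_level
GBM33	PTEN	snv	Q97*	nonsense	.
GBM33	PTEN	loss	loss	.	arm_level
GBM33	CDKN2A	loss	loss	.	focal
GBM34	EGFR	gain	gain	.	.
GBM34	PTEN	loss	loss	.	arm_level
GBM34	TP53	snv	C242S	missense	.
GBM34	TP53	snv	V143M	missense	.
GBM34	MYCN	gain	gain	.	.
GBM35	EGFR	gain	gain	.	focal
GBM35	PIK3R1	snv	L372dup	inframe_indel	.
GBM35	CDKN2A	loss	loss	.	focal
GBM35	PTEN	loss	loss	.	arm_level
GBM35	KIT	snv	A207V	missense	.
GBM36	NF1	snv	c.1062+1	splice_site	.
GBM36	TP53	snv	T211I	missense	.
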