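gene	variant_spec	disease	significance	source_id
IDH1	R132H	glioblastoma	clinically_significant	civic:IDH1-R132H-GBM
BRAF	V600E	glioblastoma	clinically_significant	civic:BRAF-V600E-GBM
BRAF	V600E	melanoma	clinically_significant	civic:BRAF-V600E-MEL
TP53	R175H	breast cancer	clinically_significant	civic:TP53-R175H-BRCA
TP53	R273C	colorectal cancer	clinically_significant	civic:TP53-R273C-CRC
PIK3CA	E542K	breast cancer	clinically_significant	civic:PIK3CA-E542K-BRCA
EGFR	amplification	glioblastoma	clinically_significant	civic:EGFR-AMP-GBM
EGFR	VIII	glioblastoma	clinically_significant	civic:EGFR-VIII-GBM
PTEN	loss	glioblastoma	clinically_significant	civic:PTEN-LOSS-GBM
CDKN2A	loss	glioblastoma	clinically_significant	civic:CDKN2A-LOSS-GBM
EGFR	T790M	lung adenocarcinoma	resistance	civic:EGFR-T790M-LUAD
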