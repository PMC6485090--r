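gene	variant_scope	variant_spec	drug	evidence_level	trial_ids	disease
PIK3R1	any_alteration	.	BKM120	clinical_trial	NCT01870726;NCT01349660	glioblastoma
PIK3CA	any_alteration	.	BKM120	clinical_trial	NCT01870726;NCT01349660	glioblastoma
MET	any_alteration	.	INC280	clinical_trial	NCT02386826	glioblastoma
MET	gain	.	Crizotinib	approved_other_disease	NCT02034981	.
EGFR	gain	.	Cetuximab	approved_other_disease	NCT01238237;NCT02573324	.
EGFR	gain	.	ABT-414	clinical_trial	NCT02423525	glioblastoma
EGFR	gain	.	ABBV-221	clinical_trial	NCT02365662	.
EGFR	any_alteration	.	Afatanib	clinical_trial	NCT01934361	.
EGFR	specific_variant	VIII	Rindopepimut	clinical_trial	NCT01480479	glioblastoma
EGFR	specific_variant	VIII	CAR-T	clinical_trial	NCT02664363	glioblastoma
PTEN	any_alteration	.	Everolimus	approved_other_disease	NCT01870726;NCT01390571	.
PTEN	any_alteration	.	Temsirolimus	clinical_trial	NCT02152982	.
PDGFRA	gain	.	Nilotinib	approved_other_disease	NCT01140568;NCT01871311	.
PDGFRA	any_alteration	.	Crenolanib	clinical_trial	NCT02626364	.
KIT	any_alteration	.	Nilotinib	approved_other_disease	NCT01140568	.
KIT	any_alteration	.	Imatinib	approved_other_disease	.	.
KDR	any_alteration	.	Bevacizumab	approved_in_disease	.	glioblastoma
SMO	any_alteration	.	Vismodegib	approved_other_disease	NCT00980343	.
NF1	any_alteration	.	MEK162	clinical_trial	NCT01885195	.
MGMT	loss	.	Temozolomide	approved_in_disease	.	glioblastoma
MDM2	gain	.	RG7112	clinical_trial	NCT01877382	.
MDM2	gain	.	RG7388	clinical_trial	NCT02143635	.
MDM2	gain	.	AMG232	clinical_trial	NCT01723020	.
CDK4	gain	.	Palbociclib	clinical_trial	NCT01227434	.
CDK4	gain	.	Ribociclib	clinical_trial	NCT02345824	.
CDKN2A	loss	.	Palbociclib	clinical_trial	NCT01390571	.
CDKN2A	loss	.	Ribociclib	clinical_trial	NCT02152982	.
IDH1	specific_variant	R132H	AG-120	clinical_trial	NCT02073994	.
IDH1	specific_variant	R132H	AG-881	clinical_trial	NCT02481154	.
IDH1	specific_variant	R132H	BAY-1436032	clinical_trial	NCT02746081	.
RPTOR	any_alteration	.	Everolimus	approved_other_disease	NCT01434602	.
RPTOR	any_alteration	.	INK128	clinical_trial	NCT02142803	.
TSC2	any_alteration	.	Everolimus	approved_other_disease	.	.
TSC2	any_alteration	.	MLN0128	clinical_trial	NCT02142803	.
STAG2	any_alteration	.	Olaparib	clinical_trial	NCT01390571	.
STAG2	any_alteration	.	Veliparib	clinical_trial	NCT02152892	.
PALB2	loss	.	Olaparib	approved_other_disease	.	.
PALB2	loss	.	Veliparib	clinical_trial	NCT02152892	.
TP53	any_alteration	.	Temsirolimus	clinical_trial	NCT00703625	.
TP53	any_alteration	.	Docetaxel	approved_other_disease	NCT00703625	.
TP53	any_alteration	.	Paclitaxel	approved_other_disease	NCT02379416	.
BRAF	specific_variant	V600E	Vemurafanib	approved_other_disease	NCT02537600	.
BRAF	specific_variant	V600E	Cobimetinib	approved_other_disease	NCT02537600	.
MYCN	gain	.	CP-0610	clinical_trial	NCT02698176	.
MYCN	gain	.	MK-8628	clinical_trial	NCT02630251	.
MYCN	gain	.	GSK2820151	clinical_trial	NCT02698176	.
TMB_HIGH	any_alteration	.	Pembrolizumab	approved_other_disease	NCT02337686	.
TMB_HIGH	any_alteration	.	Nivolumab	approved_other_disease	NCT02017717	.
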