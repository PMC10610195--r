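hsa04010	MAPK signaling pathway (synthetic membership)	KRAS	HRAS	EGFR	FGFR2	MYC	AKT1	ERBB3	MAP2K4	BRAF	RAC1
hsa04630	JAK-STAT signaling pathway (synthetic membership)	AKT1	EGFR	ERBB3	FGFR2	HRAS	JAK1	KRAS	MYC	PIK3R1	STAT3	IL6ST
hsa04151	PI3K-Akt signaling pathway (synthetic membership)	AKT1	EGFR	ERBB3	FGFR2	KRAS	PIK3R1	MTOR	PIK3CA
hsa04150	mTOR signaling pathway (synthetic membership)	AKT1	HRAS	KRAS	PIK3R1	MTOR	TSC2
hsa04510	Focal adhesion (synthetic membership)	AKT1	EGFR	HRAS	PIK3R1	RAC1	CCND1
hsa04066	HIF-1 signaling pathway (synthetic membership)	AKT1	EGFR	HRAS	EPAS1	CDKN1A
hsa04210	Apoptosis (synthetic membership)	AKT1	JAK1	KRAS	MYC	ATM	RB1
hsa04370	VEGF signaling pathway (synthetic membership)	AKT1	HRAS	KRAS	PIK3R1	RAC1	PLCG1
hsa04110	Cell cycle (synthetic membership)	MYC	SMAD4	CCND1	CDK4	RB1	ATR
hsa04915	Estrogen signaling pathway (synthetic membership)	AKT1	EGFR	HRAS	KRAS	MYC	GNAS	RXRA
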