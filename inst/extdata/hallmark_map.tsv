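hallmark	drivers	markers
proliferative signaling	AKT1,EGFR,ERBB3,FGFR2,HRAS,JAK1,KRAS,MYC	MYC
resisting cell death	AKT1,EGFR,ERBB3,FGFR2,HRAS,JAK1,KRAS,MYC	MYC
angiogenesis	AKT1,EGFR,HRAS,KRAS,SMAD4	SMAD4
invasion and metastasis	AKT1,EGFR,ERBB3,HRAS,KRAS,MYC,PIK3R1,SMAD4	PIK3R1,SMAD4
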