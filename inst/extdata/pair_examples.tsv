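compound	gene	mode	score	effect
atorvastatin	PLAUR	KD	88.31	Anti-cancer
atorvastatin	MYC	KD	99.15	Anti-cancer
ellipticine	PLAUR	KD	91.97	Anti-cancer
ellipticine	MYC	KD	90.64	Anti-cancer
pterostilbene	PLAUR	KD	95.19	Anti-cancer
pterostilbene	MYC	KD	94.29	Anti-cancer
haloperidol	PLAUR	OE	94.07	Carcinogenic
haloperidol	SMAD4	KD	98.59	Carcinogenic
phenazopyridine	PLAUR	OE	92.97	Carcinogenic
phenazopyridine	SMAD4	KD	94.41	Carcinogenic
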