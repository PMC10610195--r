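pathway	description	numerator	denominator	top10_count
hsa04010	MAPK signaling pathway	246	254	7
hsa04630	JAK-STAT signaling pathway	219	254	9
hsa04151	PI3K-Akt signaling pathway	243	254	6
hsa04150	mTOR signaling pathway	227	254	4
hsa04510	Focal adhesion	208	254	4
hsa04066	HIF-1 signaling pathway	216	254	3
hsa04210	Apoptosis	226	254	4
hsa04370	VEGF signaling pathway	219	254	4
hsa04110	Cell cycle	219	254	2
hsa04915	Estrogen signaling pathway	215	254	5
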