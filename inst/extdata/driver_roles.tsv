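gene	role
AKT1	oncogene
EGFR	oncogene
ERBB3	oncogene
FGFR2	oncogene
HRAS	oncogene
JAK1	bifunctional
KRAS	oncogene
MYC	oncogene
PIK3R1	tumor_suppressor
SMAD4	tumor_suppressor
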