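compound	direction	genes
Homatropine	suppression	AKT1,ARHGAP35,ATR,AXIN2,BTG2,CCND1,CDKN1B,CHEK2,DICER1,DNMT3A,EGFR,EPAS1,ERBB2,ERBB3,FAT1,FBXW7,FGFR2,HRAS,JAK1,KRAS,MECOM,MSH6,MYD88,PDS5B,PMS1,RAC1,RASA1,RET,RHOA,RHOB,RXRA,SF3B1,SMAD4,TCF7L2,ZBTB20,ZFP36L1
Hydralazine	suppression	ARHGAP35,B2M,BTG2,CCND1,CDK4,CDKN2C,CHEK2,EGFR,ERBB3,FLT3,KRAS,MET,NIPBL,PIK3CA,PIK3R1,PLCB4,PLCG1,RAC1,RASA1,RET,RPS6KA3,SMAD4,SMARCB1,WT1,ZBTB20
Salbutamol	suppression	ARHGAP35,ATR,BRAF,CCND1,CTNNB1,EGFR,ERBB3,ERBB4,FGFR2,HRAS,IDH2,KRAS,MAP2K4,MECOM,MEN1,MTOR,MYC,PRKAR1A,RAC1,RHOA,SF3B1,SMAD4,SMARCB1,TRAF3
Spironolactone	suppression	ARHGAP35,AXIN2,CDKN2C,EGFR,ERBB2,ERBB3,FOXQ1,GNA13,HRAS,NRAS,RHOB,SMAD4,TSC2,ZFP36L2
Aspirin	stimulation	APOB,ARHGAP35,ATXN3,AXIN2,B2M,CHEK2,EGFR,ERBB4,FLT3,FOXQ1,GNA13,GNAS,HRAS,IDH1,JAK1,MAP2K4,MECOM,MET,MYC,PIK3CA,PIK3R1,POLRMT,PPP2R1A,PSIP1,RASA1,RB1,RET,RHOB,RPL22,SMARCB1,TCF7L2,TSC1,TSC2,WT1
Atorvastatin	stimulation	ARID5B,ATM,ATR,BRCA1,CDKN1A,CDKN2C,CTNND1,ERBB3,FLT3,IL6ST,IRF2,KRAS,MECOM,MEN1,MTOR,MYC,NRAS,PIK3R1,PIM1,RHOB,RPS6KA3,RXRA,SF1,SMAD2,TSC2,WT1,ZBTB20,ZFP36L1,ZMYM2,ZNF133
Methotrexate	stimulation	AKT1,ARHGAP35,ATR,AXIN2,BRCA1,CHEK2,EGFR,ERBB3,KRAS,MAX,MECOM,MEN1,MTOR,MYC,PIK3CA,PIK3CG,RHOA,RXRA,TCF12,TCF7L2
Quinine	stimulation	ATM,BRCA1,CDKN2C,CHEK2,ERBB3,ERBB4,FGFR2,GNAS,HRAS,IRF6,MAP2K4,MAX,MECOM,MET,MTOR,NRAS,PIK3CG,PIK3R1,PRKAR1A,RAC1,RB1,SMARCB1,TNFAIP3,TSC2,TXNIP,USP9X,VHL,ZFP36L2
Simvastatin	stimulation	CDK4,CDKN1A,CDKN2C,ERBB3,IL6ST,KRAS,MAP2K4,MYC,MYD88,RAC1,RHOB,RXRA,TXNIP,ZFP36L1,ZMYM2
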