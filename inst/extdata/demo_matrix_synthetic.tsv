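compound	gene	mode	score
Homatropine	PLAUR	KD	0.9316
Homatropine	AKT1	KD	0.9606
Homatropine	ARHGAP35	KD	0.9882
Homatropine	ATR	KD	0.9052
Homatropine	AXIN2	KD	0.9701
Homatropine	BTG2	KD	0.9234
Homatropine	CCND1	KD	0.9754
Homatropine	CDKN1B	KD	0.9898
Homatropine	CHEK2	KD	0.9409
Homatropine	DICER1	KD	0.9652
Homatropine	DNMT3A	KD	0.9857
Homatropine	EGFR	KD	0.9464
Homatropine	EPAS1	KD	0.9129
Homatropine	ERBB2	KD	0.953
Homatropine	ERBB3	KD	0.9142
Homatropine	FAT1	KD	0.9834
Homatropine	FBXW7	KD	0.9733
Homatropine	FGFR2	KD	0.9839
Homatropine	HRAS	KD	0.98
Homatropine	JAK1	KD	0.9529
Homatropine	KRAS	KD	0.9293
Homatropine	MECOM	KD	0.9621
Homatropine	MSH6	KD	0.9096
Homatropine	MYD88	KD	0.9946
Homatropine	PDS5B	KD	0.968
Homatropine	PMS1	KD	0.9218
Homatropine	RAC1	KD	0.9815
Homatropine	RASA1	KD	0.9421
Homatropine	RET	KD	0.9864
Homatropine	RHOA	KD	0.9436
Homatropine	RHOB	KD	0.9901
Homatropine	RXRA	KD	0.9868
Homatropine	SF3B1	KD	0.987
Homatropine	SMAD4	KD	0.9319
Homatropine	TCF7L2	KD	0.9331
Homatropine	ZBTB20	KD	0.9304
Homatropine	ZFP36L1	KD	0.9283
Hydralazine	PLAUR	KD	0.9418
Hydralazine	ARHGAP35	KD	0.9539
Hydralazine	B2M	KD	0.9287
Hydralazine	BTG2	KD	0.9319
Hydralazine	CCND1	KD	0.9701
Hydralazine	CDK4	KD	0.939
Hydralazine	CDKN2C	KD	0.9126
Hydralazine	CHEK2	KD	0.9654
Hydralazine	EGFR	KD	0.93
Hydralazine	ERBB3	KD	0.9479
Hydralazine	FLT3	KD	0.9871
Hydralazine	KRAS	KD	0.9383
Hydralazine	MET	KD	0.9938
Hydralazine	NIPBL	KD	0.9552
Hydralazine	PIK3CA	KD	0.9477
Hydralazine	PIK3R1	KD	0.922
Hydralazine	PLCB4	KD	0.9641
Hydralazine	PLCG1	KD	0.9774
Hydralazine	RAC1	KD	0.9129
Hydralazine	RASA1	KD	0.9768
Hydralazine	RET	KD	0.9108
Hydralazine	RPS6KA3	KD	0.9722
Hydralazine	SMAD4	KD	0.9135
Hydralazine	SMARCB1	KD	0.9128
Hydralazine	WT1	KD	0.9879
Hydralazine	ZBTB20	KD	0.9908
Salbutamol	PLAUR	KD	0.9834
Salbutamol	ARHGAP35	KD	0.9504
Salbutamol	ATR	KD	0.9746
Salbutamol	BRAF	KD	0.9147
Salbutamol	CCND1	KD	0.9268
Salbutamol	CTNNB1	KD	0.9452
Salbutamol	EGFR	KD	0.9213
Salbutamol	ERBB3	KD	0.9908
Salbutamol	ERBB4	KD	0.9775
Salbutamol	FGFR2	KD	0.9859
Salbutamol	HRAS	KD	0.9634
Salbutamol	IDH2	KD	0.962
Salbutamol	KRAS	KD	0.9164
Salbutamol	MAP2K4	KD	0.9647
Salbutamol	MECOM	KD	0.978
Salbutamol	MEN1	KD	0.975
Salbutamol	MTOR	KD	0.9577
Salbutamol	MYC	KD	0.9857
Salbutamol	PRKAR1A	KD	0.9814
Salbutamol	RAC1	KD	0.941
Salbutamol	RHOA	KD	0.9856
Salbutamol	SF3B1	KD	0.9197
Salbutamol	SMAD4	KD	0.9122
Salbutamol	SMARCB1	KD	0.924
Salbutamol	TRAF3	KD	0.9158
Spironolactone	PLAUR	KD	0.9097
Spironolactone	ARHGAP35	KD	0.9356
Spironolactone	AXIN2	KD	0.9323
Spironolactone	CDKN2C	KD	0.9878
Spironolactone	EGFR	KD	0.9074
Spironolactone	ERBB2	KD	0.923
Spironolactone	ERBB3	KD	0.9091
Spironolactone	FOXQ1	KD	0.9756
Spironolactone	GNA13	KD	0.9809
Spironolactone	HRAS	KD	0.9702
Spironolactone	NRAS	KD	0.9893
Spironolactone	RHOB	KD	0.9064
Spironolactone	SMAD4	KD	0.9149
Spironolactone	TSC2	KD	0.9463
Spironolactone	ZFP36L2	KD	0.9363
Aspirin	PLAUR	OE	0.9333
Aspirin	APOB	OE	0.951
Aspirin	ARHGAP35	OE	0.9617
Aspirin	ATXN3	OE	0.9624
Aspirin	AXIN2	OE	0.9704
Aspirin	B2M	OE	0.9117
Aspirin	CHEK2	OE	0.917
Aspirin	EGFR	OE	0.9355
Aspirin	ERBB4	OE	0.9392
Aspirin	FLT3	OE	0.9504
Aspirin	FOXQ1	OE	0.9511
Aspirin	GNA13	OE	0.9461
Aspirin	GNAS	OE	0.9291
Aspirin	HRAS	OE	0.9503
Aspirin	IDH1	OE	0.9085
Aspirin	JAK1	OE	0.9376
Aspirin	MAP2K4	OE	0.9583
Aspirin	MECOM	OE	0.9726
Aspirin	MET	OE	0.955
Aspirin	MYC	OE	0.9298
Aspirin	PIK3CA	OE	0.9649
Aspirin	PIK3R1	OE	0.9494
Aspirin	POLRMT	OE	0.9457
Aspirin	PPP2R1A	OE	0.9305
Aspirin	PSIP1	OE	0.9808
Aspirin	RASA1	OE	0.9128
Aspirin	RB1	OE	0.9098
Aspirin	RET	OE	0.9828
Aspirin	RHOB	OE	0.9279
Aspirin	RPL22	OE	0.9181
Aspirin	SMARCB1	OE	0.9184
Aspirin	TCF7L2	OE	0.9409
Aspirin	TSC1	OE	0.9879
Aspirin	TSC2	OE	0.9825
Aspirin	WT1	OE	0.951
Atorvastatin	PLAUR	OE	0.961
Atorvastatin	ARID5B	OE	0.9696
Atorvastatin	ATM	OE	0.937
Atorvastatin	ATR	OE	0.9379
Atorvastatin	BRCA1	OE	0.9691
Atorvastatin	CDKN1A	OE	0.9138
Atorvastatin	CDKN2C	OE	0.9528
Atorvastatin	CTNND1	OE	0.9332
Atorvastatin	ERBB3	OE	0.9245
Atorvastatin	FLT3	OE	0.9239
Atorvastatin	IL6ST	OE	0.9129
Atorvastatin	IRF2	OE	0.9796
Atorvastatin	KRAS	OE	0.9756
Atorvastatin	MECOM	OE	0.937
Atorvastatin	MEN1	OE	0.908
Atorvastatin	MTOR	OE	0.9185
Atorvastatin	MYC	OE	0.9584
Atorvastatin	NRAS	OE	0.9655
Atorvastatin	PIK3R1	OE	0.9341
Atorvastatin	PIM1	OE	0.9238
Atorvastatin	RHOB	OE	0.9629
Atorvastatin	RPS6KA3	OE	0.9705
Atorvastatin	RXRA	OE	0.9512
Atorvastatin	SF1	OE	0.9351
Atorvastatin	SMAD2	OE	0.9292
Atorvastatin	TSC2	OE	0.932
Atorvastatin	WT1	OE	0.9736
Atorvastatin	ZBTB20	OE	0.9505
Atorvastatin	ZFP36L1	OE	0.9752
Atorvastatin	ZMYM2	OE	0.9918
Atorvastatin	ZNF133	OE	0.9917
Methotrexate	PLAUR	OE	0.9731
Methotrexate	AKT1	OE	0.9922
Methotrexate	ARHGAP35	OE	0.9231
Methotrexate	ATR	OE	0.9581
Methotrexate	AXIN2	OE	0.9847
Methotrexate	BRCA1	OE	0.9385
Methotrexate	CHEK2	OE	0.9341
Methotrexate	EGFR	OE	0.9693
Methotrexate	ERBB3	OE	0.9261
Methotrexate	KRAS	OE	0.9921
Methotrexate	MAX	OE	0.9499
Methotrexate	MECOM	OE	0.9155
Methotrexate	MEN1	OE	0.9907
Methotrexate	MTOR	OE	0.9777
Methotrexate	MYC	OE	0.9817
Methotrexate	PIK3CA	OE	0.9437
Methotrexate	PIK3CG	OE	0.9879
Methotrexate	RHOA	OE	0.9116
Methotrexate	RXRA	OE	0.9702
Methotrexate	TCF12	OE	0.9945
Methotrexate	TCF7L2	OE	0.9945
Quinine	PLAUR	OE	0.9781
Quinine	ATM	OE	0.9741
Quinine	BRCA1	OE	0.9511
Quinine	CDKN2C	OE	0.9648
Quinine	CHEK2	OE	0.9133
Quinine	ERBB3	OE	0.9838
Quinine	ERBB4	OE	0.985
Quinine	FGFR2	OE	0.9534
Quinine	GNAS	OE	0.9842
Quinine	HRAS	OE	0.983
Quinine	IRF6	OE	0.9302
Quinine	MAP2K4	OE	0.9631
Quinine	MAX	OE	0.9913
Quinine	MECOM	OE	0.9817
Quinine	MET	OE	0.9088
Quinine	MTOR	OE	0.9099
Quinine	NRAS	OE	0.9737
Quinine	PIK3CG	OE	0.9185
Quinine	PIK3R1	OE	0.9514
Quinine	PRKAR1A	OE	0.9692
Quinine	RAC1	OE	0.9051
Quinine	RB1	OE	0.9903
Quinine	SMARCB1	OE	0.9337
Quinine	TNFAIP3	OE	0.9905
Quinine	TSC2	OE	0.9726
Quinine	TXNIP	OE	0.9518
Quinine	USP9X	OE	0.9504
Quinine	VHL	OE	0.9424
Quinine	ZFP36L2	OE	0.9182
Simvastatin	PLAUR	OE	0.9683
Simvastatin	CDK4	OE	0.9763
Simvastatin	CDKN1A	OE	0.9866
Simvastatin	CDKN2C	OE	0.9445
Simvastatin	ERBB3	OE	0.9495
Simvastatin	IL6ST	OE	0.9396
Simvastatin	KRAS	OE	0.9626
Simvastatin	MAP2K4	OE	0.9422
Simvastatin	MYC	OE	0.935
Simvastatin	MYD88	OE	0.9086
Simvastatin	RAC1	OE	0.9858
Simvastatin	RHOB	OE	0.9409
Simvastatin	RXRA	OE	0.9338
Simvastatin	TXNIP	OE	0.9767
Simvastatin	ZFP36L1	OE	0.9486
Simvastatin	ZMYM2	OE	0.9917
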