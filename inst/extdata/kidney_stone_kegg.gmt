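hsa05200	pathways in cancer	HSP90AB1	JUP	MAPK1	AR	HSP90B1	BMP2	HSP90AA1	CTBP2	MMP9	CDH1	EGF	FN1
hsa04151	PI3K-Akt signaling pathway	HSP90AB1	MAPK1	HSP90B1	HSP90AA1	YWHAB	YWHAQ	EGF	YWHAE	FN1	PCK1
hsa05215	prostate cancer	HSP90AB1	MAPK1	AR	HSP90B1	HSP90AA1	EGF
hsa04114	oocyte meiosis	MAPK1	AR	YWHAB	YWHAQ	PPP3R2	YWHAE
hsa04621	NOD-like receptor signaling pathway	HSP90AB1	MAPK1	HSP90B1	HSP90AA1	TAB1
hsa04390	Hippo signaling pathway	BMP2	YWHAB	YWHAQ	CDH1	ITGB2	YWHAE
hsa04141	protein processing in endoplasmic reticulum	HSP90AB1	P4HB	HSP90B1	HSP90AA1	HSPA5	CALR
hsa05219	bladder cancer	MAPK1	MMP9	CDH1	EGF
hsa04915	estrogen signaling pathway	HSP90AB1	MAPK1	HSP90B1	HSP90AA1	MMP9
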