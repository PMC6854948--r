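GO:0070062	extracellular exosome	HSP90AB1	P4HB	A2M	BSG	APCS	HSP90AA1	MMP9	YWHAB	CDH1	ITGB2	CALR	YWHAE	PCK1	JUP	MAPK1	HSP90B1	APOA1	EIF4A1	YWHAQ	HSPA5	EGF	GAPDH	CD14	FN1
GO:0042470	melanosome	HSP90AB1	P4HB	HSP90B1	BSG	HSP90AA1	YWHAB	HSPA5	YWHAE
GO:0005925	focal adhesion	JUP	MAPK1	P4HB	HSP90B1	BSG	YWHAB	YWHAQ	CDH1	HSPA5	CALR	YWHAE
GO:0031012	extracellular matrix	JUP	P4HB	HSP90B1	HSP90AA1	APCS	EIF4A1	HSPA5	CALR	GAPDH	FN1
GO:0071682	endocytic vesicle lumen	HSP90B1	HSP90AA1	APOA1	CALR
GO:0005829	cytosol	HSP90AB1	AR	A2M	HSP90AA1	EXOC7	YWHAB	CALR	TAB1	YWHAE	PCK1	JUP	MAPK1	HSP90B1	APOA1	EIF4A1	YWHAQ	HBG2	GAPDH
GO:0005576	extracellular region	P4HB	A2M	BMP2	APCS	HSP90AA1	MMP9	CDH1	CALR	HSP90B1	APOA1	EGF	CD14	FN1
GO:0005913	cell-cell adherens junction	HSP90AB1	JUP	BSG	YWHAB	CDH1	HSPA5	YWHAE
GO:0016020	membrane	HSP90AB1	HSP90B1	BSG	HSP90AA1	EXOC7	EIF4A1	YWHAB	YWHAQ	CDH1	ITGB2	HSPA5	CALR	GAPDH	YWHAE
GO:0072562	blood microparticle	A2M	APOA1	APCS	HBG2	FN1
GO:0034663	endoplasmic reticulum chaperone complex	P4HB	HSP90B1	HSPA5
GO:0009986	cell surface	HSP90AB1	BMP2	HSP90AA1	APOA1	ITGB2	HSPA5	CALR
GO:0005788	endoplasmic reticulum lumen	P4HB	HSP90B1	APOA1	HSPA5	CALR
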