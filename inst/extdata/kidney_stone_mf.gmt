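GO:0005515	protein binding	HSP90AB1	A2M	EXOC7	MMP9	ITGB2	CDH1	CALR	APOA1	HSPA5	EGF	GAPDH	FN1	P4HB	AR	BSG	BMP2	CTBP2	HSP90AA1	YWHAB	TAB1	YWHAE	JUP	MAPK1	HSP90B1	EIF4A1	YWHAQ	CD14
GO:0001948	glycoprotein binding	HSP90AB1	HSP90AA1	CDH1	ITGB2	HSPA5	CALR
GO:0051082	unfolded protein binding	HSP90AB1	HSP90B1	HSP90AA1	APCS	HSPA5	CALR
GO:0098641	cadherin binding involved in cell-cell adhesion	HSP90AB1	JUP	BSG	YWHAB	CDH1	HSPA5	YWHAE
GO:0019899	enzyme binding	P4HB	AR	A2M	APOA1	YWHAB	HSPA5	YWHAE
GO:0023026	MHC class II protein complex binding	HSP90AB1	HSP90AA1	YWHAE
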