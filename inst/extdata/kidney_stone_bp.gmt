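GO:0022617	extracellular matrix disassembly	BSG	A2M	MMP9	CDH1	FN1
GO:0006457	protein folding	HSP90AB1	P4HB	HSP90B1	HSP90AA1	APCS	CALR
GO:0050821	protein stabilization	HSP90AB1	HSP90AA1	APOA1	CALR	GAPDH
GO:0036500	ATF6-mediated unfolded protein response	HSP90B1	HSPA5	CALR
GO:0006950	response to stress	HSP90AB1	MAPK1	HSP90B1	HSP90AA1
GO:0006898	receptor-mediated endocytosis	HSP90B1	HSP90AA1	APOA1	CALR	CD14
GO:0034975	protein folding in endoplasmic reticulum	HSP90B1	HSPA5	CALR
GO:1900034	regulation of cellular response to heat	HSP90AB1	MAPK1	HSP90AA1	YWHAE
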