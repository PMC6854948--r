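category	term_id	term_name	count	percent	p_value	benjamini	fdr_percent	genes
BP	GO:0022617	extracellular matrix disassembly	5	16.129	8.45E-06	0.00493	0.012443	BSG,A2M,MMP9,CDH1,FN1
BP	GO:0006457	protein folding	6	19.3548	1.33E-05	0.00388	0.019533	HSP90AB1,P4HB,HSP90B1,HSP90AA1,APCS,CALR
BP	GO:0050821	protein stabilization	5	16.129	8.13E-05	0.01573	0.119559	HSP90AB1,HSP90AA1,APOA1,CALR,GAPDH
BP	GO:0036500	ATF6-mediated unfolded protein response	3	9.67742	1.03E-04	0.01495	0.151433	HSP90B1,HSPA5,CALR
BP	GO:0006950	response to stress	4	12.9032	1.64E-04	0.01897	0.240659	HSP90AB1,MAPK1,HSP90B1,HSP90AA1
BP	GO:0006898	receptor-mediated endocytosis	5	16.129	1.85E-04	0.01786	0.271641	HSP90B1,HSP90AA1,APOA1,CALR,CD14
BP	GO:0034975	protein folding in endoplasmic reticulum	3	9.67742	2.22E-04	0.01839	0.326434	HSP90B1,HSPA5,CALR
BP	GO:1900034	regulation of cellular response to heat	4	12.9032	2.88E-04	0.02084	0.422888	HSP90AB1,MAPK1,HSP90AA1,YWHAE
CC	GO:0070062	extracellular exosome	24	77.4194	3.39E-14	4.40E-12	3.94E-11	HSP90AB1,P4HB,A2M,BSG,APCS,HSP90AA1,MMP9,YWHAB,CDH1,ITGB2,CALR,YWHAE,PCK1,JUP,MAPK1,HSP90B1,APOA1,EIF4A1,YWHAQ,HSPA5,EGF,GAPDH,CD14,FN1
CC	GO:0042470	melanosome	8	25.8065	1.85E-10	1.20E-08	2.16E-07	HSP90AB1,P4HB,HSP90B1,BSG,HSP90AA1,YWHAB,HSPA5,YWHAE
CC	GO:0005925	focal adhesion	11	35.4839	2.87E-10	1.24E-08	3.34E-07	JUP,MAPK1,P4HB,HSP90B1,BSG,YWHAB,YWHAQ,CDH1,HSPA5,CALR,YWHAE
CC	GO:0031012	extracellular matrix	10	32.2581	5.97E-10	1.94E-08	6.95E-07	JUP,P4HB,HSP90B1,HSP90AA1,APCS,EIF4A1,HSPA5,CALR,GAPDH,FN1
CC	GO:0071682	endocytic vesicle lumen	4	12.9032	2.01E-06	5.22E-05	0.002338	HSP90B1,HSP90AA1,APOA1,CALR
CC	GO:0005829	cytosol	18	58.0645	2.02E-06	4.38E-05	0.002354	HSP90AB1,AR,A2M,HSP90AA1,EXOC7,YWHAB,CALR,TAB1,YWHAE,PCK1,JUP,MAPK1,HSP90B1,APOA1,EIF4A1,YWHAQ,HBG2,GAPDH
CC	GO:0005576	extracellular region	13	41.9355	2.69E-06	4.99E-05	0.003128	P4HB,A2M,BMP2,APCS,HSP90AA1,MMP9,CDH1,CALR,HSP90B1,APOA1,EGF,CD14,FN1
CC	GO:0005913	cell-cell adherens junction	7	22.5807	1.00E-05	1.63E-04	0.011684	HSP90AB1,JUP,BSG,YWHAB,CDH1,HSPA5,YWHAE
CC	GO:0016020	membrane	14	45.1613	1.18E-05	1.70E-04	0.013736	HSP90AB1,HSP90B1,BSG,HSP90AA1,EXOC7,EIF4A1,YWHAB,YWHAQ,CDH1,ITGB2,HSPA5,CALR,GAPDH,YWHAE
CC	GO:0072562	blood microparticle	5	16.129	7.86E-05	0.00102	0.091484	A2M,APOA1,APCS,HBG2,FN1
CC	GO:0034663	endoplasmic reticulum chaperone complex	3	9.67742	1.34E-04	0.00158	0.155484	P4HB,HSP90B1,HSPA5
CC	GO:0009986	cell surface	7	22.5807	2.14E-04	0.00232	0.249403	HSP90AB1,BMP2,HSP90AA1,APOA1,ITGB2,HSPA5,CALR
CC	GO:0005788	endoplasmic reticulum lumen	5	16.129	2.32E-04	0.00232	0.269618	P4HB,HSP90B1,APOA1,HSPA5,CALR
MF	GO:0005515	protein binding	27	87.0968	4.47E-08	8.09E-06	5.51E-05	HSP90AB1,A2M,EXOC7,MMP9,ITGB2,CDH1,CALR,APOA1,HSPA5,EGF,GAPDH,FN1,P4HB,AR,BSG,BMP2,CTBP2,HSP90AA1,YWHAB,TAB1,YWHAE,JUP,MAPK1,HSP90B1,EIF4A1,YWHAQ,CD14
MF	GO:0001948	glycoprotein binding	6	19.3548	9.67E-08	8.75E-06	1.19E-04	HSP90AB1,HSP90AA1,CDH1,ITGB2,HSPA5,CALR
MF	GO:0051082	unfolded protein binding	6	19.3548	1.32E-06	7.96E-05	0.001626	HSP90AB1,HSP90B1,HSP90AA1,APCS,HSPA5,CALR
MF	GO:0098641	cadherin binding involved in cell-cell adhesion	7	22.5807	1.24E-05	5.62E-04	0.015318	HSP90AB1,JUP,BSG,YWHAB,CDH1,HSPA5,YWHAE
MF	GO:0019899	enzyme binding	7	22.5807	2.62E-05	9.50E-04	0.032354	P4HB,AR,A2M,APOA1,YWHAB,HSPA5,YWHAE
MF	GO:0023026	MHC class II protein complex binding	3	9.67742	3.86E-04	0.01158	0.47498	HSP90AB1,HSP90AA1,YWHAE
KEGG	hsa05200	pathways in cancer	12	38.7097	1.00E-07	1.36E-05	1.17E-04	HSP90AB1,JUP,MAPK1,AR,HSP90B1,BMP2,HSP90AA1,CTBP2,MMP9,CDH1,EGF,FN1
KEGG	hsa04151	PI3K-Akt signaling pathway	10	32.2581	3.66E-06	2.49E-04	0.004295	HSP90AB1,MAPK1,HSP90B1,HSP90AA1,YWHAB,YWHAQ,EGF,YWHAE,FN1,PCK1
KEGG	hsa05215	prostate cancer	6	19.3548	1.93E-05	8.76E-04	0.022701	HSP90AB1,MAPK1,AR,HSP90B1,HSP90AA1,EGF
KEGG	hsa04114	oocyte meiosis	6	19.3548	5.45E-05	0.00185	0.063994	MAPK1,AR,YWHAB,YWHAQ,PPP3R2,YWHAE
KEGG	hsa04621	NOD-like receptor signaling pathway	5	16.129	5.50E-05	0.0015	0.064592	HSP90AB1,MAPK1,HSP90B1,HSP90AA1,TAB1
KEGG	hsa04390	Hippo signaling pathway	6	19.3548	2.55E-04	0.00577	0.299238	BMP2,YWHAB,YWHAQ,CDH1,ITGB2,YWHAE
KEGG	hsa04141	protein processing in endoplasmic reticulum	6	19.3548	4.30E-04	0.00833	0.503915	HSP90AB1,P4HB,HSP90B1,HSP90AA1,HSPA5,CALR
KEGG	hsa05219	bladder cancer	4	12.9032	5.14E-04	0.0087	0.601459	MAPK1,MMP9,CDH1,EGF
KEGG	hsa04915	estrogen signaling pathway	5	16.129	5.40E-04	0.00813	0.632287	HSP90AB1,MAPK1,HSP90B1,HSP90AA1,MMP9
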