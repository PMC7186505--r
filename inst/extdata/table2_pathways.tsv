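id	name	p_raw	p_adjusted	genes
hsa04975	Fat digestion and absorption	5.72e-7	6.63e-5	PLPP3,APOA1,APOB,ABCG5,ABCG8
hsa04933	AGE-RAGE signaling pathway in diabetic complications	2.60e-6	1.92e-4	TGFB1,COL4A1,COL4A2,FN1,NOS3,SMAD3
hsa05200	Pathways in cancer	2.35e-5	1.12e-3	TGFB1,COL4A1,RHOA,COL4A2,CDKN2B,FN1,CXCL12,EDNRA,SMAD3
hsa04151	PI3K-Akt signaling pathway	5.86e-5	1.90e-3	COL4A1,COL4A2,EPOR,FLT1,FN1,ITGB5,NOS3,IL6R
hsa04510	Focal adhesion	1.37e-4	3.96e-3	COL4A1,RHOA,COL4A2,FLT1,FN1,ITGB5
hsa05205	Proteoglycans in cancer	1.53e-4	4.10e-3	TGFB1,RHOA,PTPN11,MRAS,FN1,ITGB5
hsa04512	ECM-receptor interaction	3.20e-4	6.30e-3	COL4A1,COL4A2,FN1,ITGB5
hsa05222	Small cell lung cancer	3.51e-4	6.32e-3	COL4A1,COL4A2,CDKN2B,FN1
hsa04350	TGF-beta signaling pathway	3.51e-4	6.32e-3	TGFB1,RHOA,CDKN2B,SMAD3
hsa05146	Amebiasis	5.83e-4	9.45e-3	TGFB1,COL4A1,COL4A2,FN1
hsa04360	Axon guidance	6.58e-4	1.03e-2	RHOA,PTPN11,FES,CXCL12,NRP1
hsa00561	Glycerolipid metabolism	1.69e-3	1.99e-2	PLPP3,LPL,ALDH2
hsa05210	Colorectal cancer	1.78e-3	2.06e-2	TGFB1,RHOA,SMAD3
hsa04068	FoxO signaling pathway	1.91e-3	2.06e-2	TGFB1,CDKN2B,SMAD3,SOD2
hsa04072	Phospholipase D signaling pathway	2.75e-3	2.45e-2	RHOA,PTPN11,MRAS,PLPP3
hsa04976	Bile secretion	2.88e-3	2.48e-2	LDLR,ABCG5,ABCG8
hsa05220	Chronic myeloid leukemia	2.88e-3	2.48e-2	TGFB1,PTPN11,SMAD3
hsa05166	HTLV-I infection	3.52e-3	2.80e-2	TGFB1,CDKN2B,MRAS,SMAD3,NRP1
hsa04144	Endocytosis	3.76e-3	2.85e-2	TGFB1,RHOA,FLT1,LDLR,SMAD3
hsa00091	phosphatidylcholine (PC) biosynthesis, PE to PC	4.03e-3	2.92e-2	PEMT
hsa04977	Vitamin digestion and absorption	4.12e-3	2.93e-2	APOA1,APOB
hsa04060	Cytokine-cytokine receptor interaction	4.42e-3	3.11e-2	TGFB1,EPOR,FLT1,IL6R,CXCL12
hsa05323	Rheumatoid arthritis	5.60e-3	3.69e-2	TGFB1,FLT1,CXCL12
hsa04066	HIF-1 signaling pathway	7.71e-3	4.77e-2	FLT1,NOS3,IL6R
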