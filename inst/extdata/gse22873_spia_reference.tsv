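block	order	pathway_id	name	status	pSize	NDE	pGFdr
GSE22873_M	1	mmu04620	Toll-like receptor signaling pathway	Inhibited	87	36	1.03E-33
GSE22873_M	2	mmu05161	Hepatitis B	Inhibited	149	36	1.20E-24
GSE22873_M	3	mmu05140	Leishmaniasis	Inhibited	66	23	9.51E-20
GSE22873_M	4	mmu05152	Tuberculosis	Inhibited	158	32	2.20E-19
GSE22873_M	5	mmu04621	NOD-like receptor signaling pathway	Inhibited	148	30	6.91E-18
GSE22873_M	6	mmu05162	Measles	Inhibited	131	28	6.91E-18
GSE22873_M	7	mmu05142	Chagas disease (American trypanosomiasis)	Inhibited	99	23	4.43E-15
GSE22873_M	8	mmu05169	Epstein-Barr virus infection	Inhibited	185	29	1.16E-14
GSE22873_M	9	mmu05164	Influenza A	Inhibited	143	26	1.40E-14
GSE22873_M	10	mmu05145	Toxoplasmosis	Inhibited	105	22	2.62E-14
GSE22873_M	11	mmu05170	Human immunodeficiency virus 1 infection	Inhibited	194	28	2.16E-13
GSE22873_M	12	mmu05135	Yersinia infection	Inhibited	116	22	7.84E-13
GSE22873_M	13	mmu05133	Pertussis	Inhibited	67	17	2.36E-12
GSE22873_M	14	mmu04064	NF-kappa B signaling pathway	Inhibited	92	18	1.94E-10
GSE22873_M	15	mmu05168	Herpes simplex virus 1 infection	Inhibited	340	31	3.64E-10
GSE22873_M	16	mmu05132	Salmonella infection	Inhibited	193	24	5.73E-10
GSE22873_M	17	mmu05134	Legionellosis	Inhibited	51	13	2.56E-09
GSE22873_M	18	mmu05235	PD-L1/PD-1 checkpoint pathway in cancer	Inhibited	84	15	1.38E-08
GSE22873_M	19	mmu04010	MAPK signaling pathway	Inhibited	281	25	3.65E-07
GSE22873_M	20	mmu05144	Malaria	Inhibited	48	9	1.23E-05
GSE22873_M	21	mmu05143	African trypanosomiasis	Inhibited	31	7	0.000126
GSE22873_MA	1	mmu05170	Human immunodeficiency virus 1 infection	Inhibited	194	61	2.18E-50
GSE22873_MA	2	mmu04620	Toll-like receptor signaling pathway	Inhibited	87	44	1.24E-45
GSE22873_MA	3	mmu05169	Epstein-Barr virus infection	Activated	185	53	8.65E-41
GSE22873_MA	4	mmu05142	Chagas disease (American trypanosomiasis)	Inhibited	99	35	2.30E-29
GSE22873_MA	5	mmu05162	Measles	Inhibited	131	38	1.42E-28
GSE22873_MA	6	mmu05161	Hepatitis B	Inhibited	149	40	1.63E-28
GSE22873_MA	7	mmu05135	Yersinia infection	Inhibited	116	35	1.61E-26
GSE22873_MA	8	mmu05235	PD-L1/PD-1 checkpoint pathway in cancer	Inhibited	84	31	1.94E-26
GSE22873_MA	9	mmu05168	Herpes simplex virus 1 infection	Inhibited	340	50	6.55E-24
GSE22873_MA	10	mmu04621	NOD-like receptor signaling pathway	Activated	148	33	1.24E-20
GSE22873_MA	11	mmu05140	Leishmaniasis	Inhibited	66	23	3.92E-19
GSE22873_MA	12	mmu05164	Influenza A	Inhibited	143	31	7.33E-19
GSE22873_MA	13	mmu05152	Tuberculosis	Inhibited	158	31	1.74E-17
GSE22873_MA	14	mmu05133	Pertussis	Inhibited	67	21	2.00E-16
GSE22873_MA	15	mmu05145	Toxoplasmosis	Inhibited	105	23	1.60E-14
GSE22873_MA	16	mmu04064	NF-kappa B signaling pathway	Inhibited	92	22	5.09E-14
GSE22873_MA	17	mmu05132	Salmonella infection	Inhibited	193	26	5.18E-11
GSE22873_MA	18	mmu04933	AGE-RAGE signaling pathway in diabetics	Activated	98	18	1.58E-09
GSE22873_MA	19	mmu05134	Legionellosis	Inhibited	51	13	7.03E-09
GSE22873_MA	20	mmu04010	MAPK signaling pathway	Inhibited	281	22	6.66E-06
GSE22873_MA	21	mmu05144	Malaria	Inhibited	48	9	2.00E-05
GSE22873_MA	22	mmu05143	African trypanosomiasis	Inhibited	31	7	0.000149
GSE22873_MA	23	mmu05010	Alzheimer disease	Activated	311	13	0.158326
GSE22873_A	1	mmu04933	AGE-RAGE signaling pathway in diabetics	Activated	98	10	0.002314
GSE22873_A	2	mmu05150	Staphylococcus aureus infection	Activated	76	3	0.476408
GSE22873_A	3	mmu05010	Alzheimer disease	Activated	311	8	0.638874
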