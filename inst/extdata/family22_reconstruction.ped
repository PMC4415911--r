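Family	Individual	Father	Mother	Sex	Phenotype	CancerType	AgeDx	Proband	BRCA1:c.2110_2111delAA	MSH3:c.162_179del18	MUTYH:c.850-2A>G
22	MGF	0	0	1	2	Breast	68	0	0	0	0
22	MGM	0	0	2	1	0	0	0	0	0	0
22	FTH	0	0	1	1	0	0	0	w/w	M/w	w/w
22	MTH	MGF	MGM	2	2	Breast;Lymphoma	60,61	0	M/w	M/w	0
22	A1	MGF	MGM	2	2	Breast	49	0	M/w	M/w	0
22	A2	MGF	MGM	2	2	Breast	34	0	M/w	M/w	0
22	A3	MGF	MGM	2	2	Breast	50	0	M/w	w/w	0
22	PB	FTH	MTH	2	2	Breast	37	1	M/w	M/w	M/w
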