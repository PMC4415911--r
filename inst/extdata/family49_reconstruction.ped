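Family	Individual	Father	Mother	Sex	Phenotype	CancerType	AgeDx	Proband	MSH3:c.199_207del9
49	MGF	0	0	1	2	Stomach	70	0	0
49	MGM	0	0	2	1	0	0	0	0
49	FTH	0	0	1	1	0	0	0	0
49	MTH	MGF	MGM	2	2	Breast;Colon	45,50	0	M/w
49	AUNT	MGF	MGM	2	2	Colon	45	0	M/w
49	UNC	MGF	MGM	1	2	Rectum	50	0	M/w
49	PB	FTH	MTH	2	2	Breast;Ovary	32	1	M/w
49	SIS	FTH	MTH	2	2	Breast	38	0	M/w
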