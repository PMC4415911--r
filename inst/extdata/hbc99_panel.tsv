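Gene	Inheritance	Category
BRCA1	dominant	BRCA
BRCA2	dominant	BRCA
TP53	dominant	TP53
MLH1	dominant	MMR
MLH3	dominant	MMR
MSH3	dominant	MMR
CDH1	dominant	CDH1
RAD50	dominant	FA
PALB2	dominant	FA
FANCD2	dominant	FA
FANCI	dominant	FA
SLX4	dominant	FA
RAD51C	dominant	FA
RGSL1	dominant	OTHER
CDKN2A	dominant	OTHER
SPINK1	dominant	OTHER
TNFRSF13B	dominant	OTHER
FGFR3	dominant	OTHER
WRN	recessive	OTHER
MUTYH	recessive	OTHER
CYP17A1	recessive	OTHER
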