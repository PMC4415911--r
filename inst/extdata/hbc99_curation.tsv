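Gene	cDNA	Evidence	Source
BRCA2	c.7007G>A	database	BIC
TP53	c.523C>G	database	p53 mutation database R16
TP53	c.839G>C	database	p53 mutation database R16
MLH1	c.194G>A	literature	published Lynch-syndrome case report
CDH1	c.1296C>G	literature	gastric cancer exon9-skipping report
MUTYH	c.850-2A>G	literature	MUTYH-associated polyposis breast-cancer risk study
WRN	c.4245dupT	literature	WRN heterozygote breast-cancer association study
CYP17A1	c.987delC	literature	early-onset breast cancer sibship report
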