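TP53_PATHWAY	synthetic stand-in membership; edit to taste	TP53	MDM2	MDM4	ATM	CHEK2	RPS6KA3
WNT_PATHWAY	synthetic stand-in membership; edit to taste	CTNNB1	APC	AXIN1	AXIN2	TCF7L2	RNF43
PI3K_PATHWAY	synthetic stand-in membership; edit to taste	PIK3CA	PTEN	AKT1	MAP3K1	MAP2K4	PIK3R1
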