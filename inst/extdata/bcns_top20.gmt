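BCNS_TOP20_UP	top-10 genes elevated with tumor necrosis	ART3	PSAT1	ROPN1	SOX11	MMP12	PPP1R14C	ROPN1B	HORMAD1	CXCL1	LEMD1
BCNS_TOP20_DN	top-10 genes reduced with tumor necrosis	AGR3	C1orf64	ESR1	SCUBE2	FOXA1	AGR2	NAT1	GFRA1	SCGB2A2	TBC1D9
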