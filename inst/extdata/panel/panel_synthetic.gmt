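STATHMIN	editable stand-in; replace with the published gene list	STMN1
PCNA_PROLIFERATION	editable stand-in; replace with the published gene list	PCNA	MKI67	MCM2	RRM2	TYMS	TOP2A
ONCOTYPE_PROLIF	editable stand-in; replace with the published gene list	MKI67	AURKA	BIRC5	CCNB1	MYBL2
HYPOXIA_UP	editable stand-in; replace with the published gene list	CA9	VEGFA	SLC2A1	LDHA	PGK1	ADM	NDRG1
NESTIN	editable stand-in; replace with the published gene list	NES
EMT_UP	editable stand-in; replace with the published gene list	VIM	ZEB1	SNAI1	SNAI2	TWIST1	CDH2
EMT_DN	editable stand-in; replace with the published gene list	CDH1	CLDN4	CLDN7	DSP
LUMINAL_PROGENITOR	editable stand-in; replace with the published gene list	KIT	ELF5	CD14	ALDH1A3
LUMINAL_MATURE	editable stand-in; replace with the published gene list	ESR1	FOXA1	GATA3	AR	PGR
MAMMARY_STEM	editable stand-in; replace with the published gene list	ITGA6	ITGB1	KRT5	KRT14	TP63
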