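IMMUNE_SIGNATURE	curated immune-cell infiltration markers	CD8A	CD8B	CD3D	CD3E	CD3G	CD2	GZMA	GZMB	GZMK	PRF1	NKG7	CCL5	CXCL9	CXCL10	CXCL11	IDO1	LAG3	PDCD1	CTLA4	TIGIT	HAVCR2	CD274	IFNG	STAT1	TAP1	TAP2	HLA-A	HLA-B	HLA-DRA	HLA-DPB1	B2M	IRF1	TBX21	EOMES	IL2RB	KLRD1	SH2D1A	CD27	ICOS	TNFRSF9
STROMAL_SIGNATURE	curated stromal / fibroblast markers	COL1A1	COL1A2	COL3A1	COL5A1	COL5A2	COL6A3	FAP	ACTA2	PDGFRA	PDGFRB	FN1	THBS2	POSTN	LUM	DCN	VCAN	SPARC	FBN1	MMP2	TIMP3	TAGLN	MYL9	CALD1	TPM2	ZEB1	SNAI2	TWIST1	TGFB1	TGFB3	INHBA	CTGF	SFRP2	SFRP4	OLFML3	GREM1	COL10A1	COL11A1	COMP	SULF1	FBLN1
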