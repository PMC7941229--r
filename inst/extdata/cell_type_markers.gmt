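T_cells	T-cell lineage markers	CD3D	CD3E	CD3G	CD2	CD5	CD6	TRAC	TRBC1	IL7R	LCK
CD8_T_cells	cytotoxic T-cell markers	CD8A	CD8B	GZMK	GZMA	NKG7
B_cells	B-cell markers	CD19	MS4A1	CD79A	CD79B	BLK	TCL1A
NK_cells	natural-killer markers	KLRD1	KLRF1	NCR1	KIR2DL3	GNLY	XCL1
M1	classically activated macrophage markers	NOS2	IL12B	CXCL9	CXCL10	CXCL11	TNF	IL1B	SOCS3
M2	alternatively activated macrophage markers	MRC1	CD163	MSR1	IL10	CCL22	TGM2	ARG1	CLEC7A
Fibroblasts	fibroblast markers	COL1A1	COL3A1	FAP	PDGFRB	ACTA2	DCN
Endothelial	endothelial markers	PECAM1	VWF	CDH5	KDR	TEK	CLDN5
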