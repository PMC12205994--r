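ifn_signaling	illustrative interferon-signalling gene set (gene symbols)	STAT1	STAT2	IRF1	IRF7	IRF9	IFNAR1	IFNAR2	IFNGR1	IFNGR2	OAS1	OAS2	MX1	MX2	ISG15	IFIT1	IFIT3	GBP1	GBP2
tcell_cytokine_receptors	illustrative T-cell-activating cytokine receptor set	IL2RA	IL2RB	IL2RG	IL7R	IL12RB1	IL12RB2	IL15RA	IL18R1	IL21R	IL27RA	CXCR3	CCR5	CCR7
cytotoxic_effectors	illustrative cytotoxic effector molecule set	GZMA	GZMB	GZMH	GZMK	PRF1	GNLY	NKG7	KLRD1	KLRK1	FASLG	IFNG	TNF
antigen_presentation	illustrative antigen processing and presentation set	HLA-A	HLA-B	HLA-C	HLA-DRA	HLA-DRB1	HLA-DPA1	HLA-DQA1	B2M	TAP1	TAP2	TAPBP	PSMB8	PSMB9
checkpoint_regulators	illustrative immune checkpoint set	CD274	PDCD1	PDCD1LG2	CTLA4	LAG3	HAVCR2	TIGIT	IDO1	BTLA
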