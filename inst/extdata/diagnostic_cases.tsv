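case_id	gene	cohort	mei_class	tools
case01	APC	Radboudumc	L1	MELT,SCRAMble
case02	AVPR2	Radboudumc	L1	MELT,SCRAMble
case03	BRCA2	Radboudumc	Alu	MELT
case04	CC2D2A	Radboudumc	Alu	MELT
case05	COL11A1	Radboudumc	unknown	SCRAMble
case06	COL6A2	Solve-RD	Alu	MELT,SCRAMble
case07	NIPBL	Solve-RD	Alu	MELT,SCRAMble
case08	NKX2-1	Solve-RD	Alu	SCRAMble
case09	TTN	Radboudumc	Alu	MELT,SCRAMble
case10	USH2A	Radboudumc	Alu	SCRAMble
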