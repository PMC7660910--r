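# DTU events whose parent gene was also detected by gene-level DGE (BH FDR < 0.05).
# Effect sizes (ES) are relative to controls: positive = increased in cases.
tool	gene	transcript_id	biotype	es_dtu	es_dge
DRIMSeq	BCHE	ENST00000540653	protein coding	1.81	-0.96
DRIMSeq	BCHE	ENST00000264381	protein coding	-1.81	-0.96
DEXSeq	DAAM2	ENST00000491083	processed transcript	0.99	-0.80
DRIMSeq	EAF1-AS1	ENST00000610011	antisense	2.79	0.99
DRIMSeq	FRG1B	ENST00000439954	protein coding	-0.77	-1.26
DRIMSeq	FRG1B	ENST00000358464	protein coding	-0.79	-1.26
DRIMSeq	FRG1B	ENST00000479318	nonsense mediated decay	1.13	-1.26
DRIMSeq	FRMPD2	ENST00000491130	retained intron	-2.97	-1.17
DRIMSeq	FRMPD2	ENST00000486151	retained intron	2.97	-1.17
DRIMSeq	HIBCH	ENST00000414928	nonsense mediated decay	1.58	0.88
DRIMSeq	MIA	ENST00000597600	protein coding	-2.08	1.43
DRIMSeq	MIA	ENST00000593317	retained intron	2.08	1.43
DRIMSeq	MMP24-AS1	ENST00000566203	antisense	0.91	-0.58
DRIMSeq	PRODH	ENST00000334029	protein coding	-1.48	-1.17
DRIMSeq	SLCO1A2	ENST00000452078	protein coding	-0.83	-1.04
DRIMSeq	SLCO1A2	ENST00000463718	retained intron	0.83	-1.04
DRIMSeq	TSPAN15	ENST00000475069	retained intron	2.32	-0.84
DRIMSeq	TSPAN15	ENST00000373290	protein coding	-2.32	-0.84
DRIMSeq	UFSP2	ENST00000509180	protein coding	1.22	-0.60
DRIMSeq	VWF	ENST00000538635	processed transcript	-1.38	-0.93
DRIMSeq	VWF	ENST00000261405	protein coding	1.38	-0.93
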