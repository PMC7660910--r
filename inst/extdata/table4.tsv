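# Replicated DTU events: significant after FWER control in the discovery
# cohort, concordant in direction and nominally significant in the
# replication cohort. Effect sizes (ES) relative to controls.
tool	gene	transcript_id	biotype	es_discovery	es_replication
DEXSeq	BCHE	ENST00000264381	protein coding	-1.78	-1.16
DEXSeq	BCHE	ENST00000540653	protein coding	1.79	1.16
DEXSeq	XPA	ENST00000375128	protein coding	-1.18	-0.82
DEXSeq	VWA9	ENST00000573314	nonsense mediated decay	-1.81	-0.86
DRIMSeq	SLC16A1	ENST00000369626	protein coding	-1.02	-0.91
DRIMSeq	SLC16A1	ENST00000478835	processed transcript	1.02	0.91
DRIMSeq	THEM5	ENST00000453881	protein coding	1.74	1.77
DRIMSeq	THEM5	ENST00000368817	protein coding	-1.74	-1.77
DRIMSeq	BCHE	ENST00000540653	protein coding	1.81	1.06
DRIMSeq	BCHE	ENST00000264381	protein coding	-1.81	-1.06
DRIMSeq	HDAC3	ENST00000305264	protein coding	-1.38	-0.63
DRIMSeq	XPA	ENST00000375128	protein coding	-1.15	-0.78
DRIMSeq	ZNF208	ENST00000601993	protein coding	1.13	1.07
DRIMSeq	VWA9	ENST00000573314	nonsense mediated decay	-1.70	-0.81
DRIMSeq	SLC2A4RG	ENST00000473157	processed transcript	-2.30	-2.09
DRIMSeq	CD46	ENST00000367041	protein coding	-1.25	-0.59
DRIMSeq	ST3GAL5	ENST00000393808	protein coding	-0.96	-0.54
DRIMSeq	ACO1	ENST00000379923	protein coding	-1.38	-1.83
DRIMSeq	PRODH	ENST00000334029	protein coding	-1.48	-1.39
DRIMSeq	RPS9	ENST00000391752	protein coding	2.56	0.95
DRIMSeq	LRTOMT	ENST00000440313	protein coding	1.41	0.68
DRIMSeq	LINC00499	ENST00000510736	lincRNA	-1.14	-0.68
DRIMSeq	RNF38	ENST00000377885	protein coding	-0.98	-0.87
DRIMSeq	APIP	ENST00000527830	processed transcript	-2.87	-2.49
DRIMSeq	CNPY2	ENST00000548013	retained intron	-0.79	-0.31
DRIMSeq	LINC00499	ENST00000502757	lincRNA	0.93	0.54
DRIMSeq	ACAA1	ENST00000452171	protein coding	-1.26	-0.83
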