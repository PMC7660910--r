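# Illustrative cortical cell-type marker gene sets (canonical marker symbols,
# for examples and tests; not a curated reference panel).
cell_type	gene_id
neuron	RBFOX3
neuron	SNAP25
neuron	SYT1
neuron	GAD1
neuron	SLC17A7
oligodendrocyte	MBP
oligodendrocyte	PLP1
oligodendrocyte	MOG
oligodendrocyte	MOBP
oligodendrocyte	MAG
astrocyte	GFAP
astrocyte	AQP4
astrocyte	ALDH1L1
astrocyte	SLC1A2
astrocyte	S100B
microglia	AIF1
microglia	CX3CR1
microglia	P2RY12
microglia	TMEM119
microglia	CSF1R
endothelial	CLDN5
endothelial	PECAM1
endothelial	FLT1
endothelial	VWF
endothelial	TEK
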