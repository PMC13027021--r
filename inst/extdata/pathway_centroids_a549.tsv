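pathway	n_genes	r40	r80	r300	example_genes
Cytokine/inflammation	7	0.908	0.955	1.567	IL6;CXCL8;PTGS2
Cell survival	11	0.874	0.936	1.476	TP53;BCL2;BIRC5
Invasion & ECM remodeling	12	0.847	0.923	1.469	CD44;MMP9;MUC1
PI3K-AKT axis	11	0.880	0.971	1.468	AKT2;PIM1;IGF1
Transcriptional amplifiers	14	0.868	0.931	1.442	MYC;MYCN;STAT3
RAS-MAPK core	11	0.842	0.954	1.440	HRAS;NRAS;RAF1
DNA repair & stress tolerance	5	0.842	0.940	1.402	ERCC2;MSH6;XPC
RTKs & adaptors	14	0.959	0.948	1.377	EGFR;ERBB2;FGFR1
Cell cycle & replication	16	0.885	0.940	1.371	CCND1;TERT;CDK4
Drug Metabolism and Transport	1	1.122	0.585	1.268	ABCB1
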