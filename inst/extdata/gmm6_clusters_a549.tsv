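cluster	label	r40	r80	r300	genes
1	Cellular Regulation and Genomic Stability	0.906	0.984	1.666	CDC25C;ERBB3;ITGB1;LAMB1;MSH6;MYC;NQO1;PPARG;PTEN;RB1;STAT3;TERT;TFRC;TGFBI;TIMP2;TOP1;XRCC5
2	KRAS Effector and Hypoxic Response Module	0.792	0.929	1.565	BCL2A1;CCNE1;CD44;EGFR;ETV6;FAT1;GADD45A;HIF1A;HSP90AB1;CXCL8;KMT2A;PGK1;PLAUR;RAD54L;RAF1;SFPQ;TPR;YY1
3	TP53 Homeostatic Hub	0.982	0.975	1.460	CAV1;CCND1;CEBPA;ERBB2;FOSL2;IGF1;JUN;MST1R;PCNA;PIM1;RARA;SIAH1;TP53
4	Accessory Growth Signals	0.820	0.952	1.343	BCL2;BCR;CDC25B;ETS1;ETS2;FAS;FGF2;IGFBP3;IRF1;LYN;MET;NRAS;PDGFA;PTPRG;SERPINE1;TYMS;XPC
5	Invasion and Phenotypic Plasticity	0.957	0.903	1.264	BCL2L1;CCND3;CSK;HRAS;IGFBP2;NUMA1;S100A4;TGFB1;TYRO3
6	Basal Maintenance and Survival Reserve	0.830	0.897	1.180	AKT2;BIRC5;CDK2;CDK4;CDKN1A;CDKN2C;E2F1;ERCC2;FANCG;FGFR3;MTA1;MUC1;MYBL2;NPM1;CDK16;RET;TFE3
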