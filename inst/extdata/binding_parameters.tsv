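id	ligand	construct	K_d	n	dH	dS
rna_wt	RNA_aptamer	TetR	5.6	0.96	-156.0	-365.2
rna_q38a	RNA_aptamer	TetR-Q38A	26.2	1.10	-152.8	-367.2
rna_y42a	RNA_aptamer	TetR-Y42A	13900	1	-74.6	-157.1
dna_wt	tetO_dsDNA	TetR	51.1	1.17	57.7	336.4
dna_q38a	tetO_dsDNA	TetR-Q38A	432.7	1.11	53.4	300.9
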