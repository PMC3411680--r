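order_label	n_families	n_copies	n_full_length	n_incomplete	dna_mb
ERV	1	7	4	3	0.03
Copia	46	3382	57	3325	2.23
Gypsy	27	3085	47	3038	1.71
LARD	3	118	1	117	0.05
DIRS	1	19	1	18	0.01
Tad	2	22	17	5	1.6
Deceiver	1	1	1	0	0.02
L1	1	1	0	1	0.01
LINE	5	1249	5	1244	0.58
TIR	23	6369	692	5677	2.85
Helitron	1	215	2	213	0.08
MITE	4	249	103	146	0.06
unclassified	56	11070	NA	NA	5.33
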