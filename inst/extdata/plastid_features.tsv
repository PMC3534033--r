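feature	Egra	Elon	Maen	Evir	Egym	Ppar
at_percent	73.9	77.6	70.6	71.4	65.7	65.3
total_bp	143171	73345	74746	65513	67622	101605
genes_bp	62776	49860	45568	44061	50573	80191
intergenic_bp	24712	11357	13048	9288	10176	18657
introns_bp	55683	12128	16130	12164	6873	2757
coding_pct	43.8	68.0	61.0	67.3	74.8	78.9
intergenic_pct	17.3	15.5	17.5	14.2	15.0	18.4
intronic_pct	38.9	16.5	21.6	18.6	10.2	2.7
genes_total	88	57	87	84	86	110
protein_coding	58	27	58	56	58	81
tRNAs	27	27	27	25	26	27
rRNAs	3	3	2	3	2	2
insertion_sites	139	60	53	23	7	1
intron_orfs	4	0	3	3	4	1
rrna_operons	3	3	1	2	2	2
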