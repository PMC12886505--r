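bin	total_genes	n_up	n_down	n_unchanged
7	28744	71	91	28582
8	14237	69	58	14110
9	3847	18	21	3808
10	943	5	8	930
11	185	2	0	183
12	28	1	0	27
13	13	0	0	13
14	8	0	0	8
15	0	0	0	0
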