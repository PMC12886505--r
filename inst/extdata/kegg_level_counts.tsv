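transcriptome	level	total_genes	n_up	n_down	n_unchanged
nymph	1	35	17	18	0
nymph	2	280	47	40	193
nymph	3	103	23	22	58
adult	1	65	15	16	34
adult	2	144	30	25	89
adult	3	198	27	17	154
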