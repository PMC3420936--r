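strain	position	genotype	eff_pct	eff_sd_pct	mif
NH6206	85	rpoC_del215_220	97	1	0.83
NH6207	71	rpoC_del215_220	86	7	0.95
NH6208	58	rpoC_del215_220	82	15	0.98
NH6209	45	rpoC_del215_220	92	2	0.79
NH6210	33	rpoC_del215_220	68	5	0.66
NH6211	21	rpoC_del215_220	86	7	1.07
NH6212	9	rpoC_del215_220	86	2	0.84
NH6213	96	rpoC_del215_220	88	2	0.96
NH6214	57.65	rpoC_del215_220	83	4	0.90
NH6215	57.64	rpoC_del215_220	69	5	0.41
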