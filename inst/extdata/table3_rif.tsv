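strain	position	genotype	eff_pct	eff_sd_pct	censored	mif	mif_bound	eff_rif_pct	eff_rif_sd_pct	delta_sigma_rif
NH6037	85	gyrB1820	8	6	0	9	0	56	5	-0.020
NH6108	71	gyrB1820	NA	NA	1	80	1	11	6	-0.012
NH6109	58	gyrB1820	NA	NA	1	80	1	57	2	-0.030
NH6110	45	gyrB1820	1	1	0	73	1	22	7	-0.018
NH6111	33	gyrB1820	NA	NA	1	45	1	2	1	-0.004
NH6112	21	gyrB1820	1	1	0	90	0	19	6	-0.016
NH6113	9	gyrB1820	NA	NA	1	73	1	11	2	-0.012
NH6114	96	gyrB1820	NA	NA	1	85	1	9	5	-0.011
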