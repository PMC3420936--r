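strain	genotype	doubling_min	doubling_sd_min	eff_pct	eff_sd_pct	sigma_d	mif
NH6000	WT	39	1	81	3	-0.038	1
NH6016	gyrA213	39	1	58	1	-0.032	1.4
NH6019	gyrA209	45	3	30	13	-0.026	2.7
NH6028	gyrB652	53	3	7	3	-0.010	12
NH6037	gyrB1820	58	4	8	6	-0.011	10
NH6040	parC281	39	1	76	1	-0.037	1.1
NH6043	parE206	52	2	59	4	-0.032	1.4
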