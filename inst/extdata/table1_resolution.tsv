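strain	position	genotype	eff_pct	eff_sd_pct	censored	mif	mif_bound	sigma_d	sigma_bound
NH3868	57.65	WT	75	6	0	1	0	-0.037	0
NH4028	57.64	WT	28	3	0	1	0	-0.023	0
NH6000	85	WT	81	4	0	1	0	-0.038	0
NH6001	71	WT	82	2	0	1	0	-0.038	0
NH6002	58	WT	80	3	0	1	0	-0.038	0
NH6003	45	WT	73	6	0	1	0	-0.036	0
NH6005	33	WT	45	6	0	1	0	-0.022	0
NH6006	21	WT	92	2	0	1	0	-0.041	0
NH6007	9	WT	73	12	0	1	0	-0.036	0
NH6008	96	WT	85	3	0	1	0	-0.040	0
NH6016	85	gyrA213	58	1	0	1.4	0	-0.032	0
NH6019	85	gyrA209	30	12	0	3	0	-0.024	0
NH6020	71	gyrA209	30	6	0	3	0	-0.024	0
NH6021	58	gyrA209	26	9	0	3	0	-0.022	0
NH6022	45	gyrA209	17	5	0	5	0	-0.018	0
NH6024	33	gyrA209	9	4	0	5	0	-0.013	0
NH6025	21	gyrA209	20	13	0	5	0	-0.019	0
NH6026	9	gyrA209	30	3	0	2	0	-0.020	0
NH6027	96	gyrA209	48	5	0	2	0	-0.030	0
NH6028	85	gyrB652	7	3	0	12	0	-0.012	0
NH6029	71	gyrB652	NA	NA	1	80	1	-0.003	1
NH6030	58	gyrB652	2	1	0	40	0	-0.004	0
NH6031	45	gyrB652	NA	NA	1	70	1	-0.003	1
NH6033	33	gyrB652	NA	NA	1	45	1	-0.003	1
NH6034	21	gyrB652	NA	NA	1	90	1	-0.003	1
NH6035	9	gyrB652	NA	NA	1	70	1	-0.003	1
NH6036	96	gyrB652	3	1	0	28	0	-0.007	0
NH6040	85	parC281	76	1	0	1.1	0	-0.037	0
NH6043	85	parE206	59	4	0	1.4	0	-0.033	0
NH6044	71	parE206	66	4	0	1.2	0	-0.034	0
NH6045	58	parE206	64	3	0	1.1	0	-0.034	0
NH6046	45	parE206	60	6	0	0.8	0	-0.032	0
NH6048	33	parE206	27	2	0	1.7	0	-0.021	0
NH6049	21	parE206	58	3	0	1.6	0	-0.032	0
NH6056	9	parE206	51	4	0	1.4	0	-0.030	0
NH6058	96	parE206	63	4	0	1.3	0	-0.033	0
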