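contig_id	DF	DR	RF	RR	nS	SnE	SE	excluded
SSHrefM3_contig_8638	0.00	6.93	0.95	0.00	-DRRF-	-DRRF-	-DRRF-	FALSE
SSHrefM3_contig_9592	0.00	72.41	2.55	0.00	-DRRF-	-DRRF-	-DRRF-	FALSE
SSHrefA3_contig_507	1.83	0.00	28.37	6.04	DF-RFRR	DF-rfRR	DF-rfRR	FALSE
SSHrefM3_contig_698	1.78	0.00	2.08	1.75	DF-RFRR	DF-rfRR	DF-rfRR	FALSE
SSHrefM3_contig_7860	3.75	0.00	0.16	2.02	DF-RFRR	DF-rfRR	DF-rfRR	FALSE
SSHrefM3_contig_1729	4.08	38.65	30.9	4.44	DFDRRFRR	dfdrrfrr	dfDRRFrr	FALSE
SSHrefM3_contig_2464	6.84	72.93	50.44	45.03	DFDRRFRR	dfdrrfrr	dfDRRFrr	TRUE
SSHrefM3_contig_7685	14.12	0.00	1.83	12.68	DF-RFRR	DF-rfRR	DF-rfRR	FALSE
SSHrefM3_contig_6945	18.83	0.00	1.22	5.20	DF-RFRR	DF-rfRR	DF-rfRR	FALSE
SSHrefM3_contig_564	24.31	24.58	58.03	32.24	DFDRRFRR	dfdrrfrr	dfDRRFrr	TRUE
SSHrefW3_contig_1414	26.38	3.18	45.65	95.31	DFDRRFRR	dfdrrfrr	DFdrrfRR	FALSE
SSHrefM3_contig_2299	42.16	0.71	38.99	75.21	DFDRRFRR	dfdrrfrr	DFdrrfRR	FALSE
SSHrefM3_contig_3336	48.95	0.81	31.29	120.42	DFDRRFRR	dfdrrfrr	DFdrrfRR	FALSE
SSHrefA3_contig_859	517.36	0.00	24.83	36.76	DF-RFRR	DF-rfRR	DF-rfRR	FALSE
SSHrefM3_contig_3263	734.40	5.33	427.96	824.25	DFDRRFRR	dfdrrfrr	DFdrrfRR	FALSE
SSHrefW3_contig_2289	1803.00	9.89	625.81	2253.85	DFDRRFRR	dfdrrfrr	DFdrrfRR	FALSE
SSHrefM3_contig_3795	3441.00	39.97	1314.08	3279.21	DFDRRFRR	dfdrrfrr	DFdrrfRR	FALSE
SSHrefM3_contig_3892	8341.00	0.21	380.12	6350.87	DFDRRFRR	dfdrrfrr	DFdrrfRR	FALSE
SSHrefM3_contig_611	34441.00	194.20	44141.60	40870.28	DFDRRFRR	dfdrrfrr	DFdrrfRR	FALSE
SSHrefM3_contig_329	71963.76	16.78	18516.37	64957.88	DFDRRFRR	dfdrrfrr	DFdrrfRR	FALSE
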