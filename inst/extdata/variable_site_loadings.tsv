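site	modification	pc1	pc2	pc3	pc4
Thr_CGT1_48	m5C	-0.99	-0.09	0.07	0.02
Ser_AGA_TGA_49	m5C	-0.98	0.10	0.09	-0.02
Lys_TTT_49	m5C	-0.98	0.14	0.05	0.06
Tyr_GTA1_48	m5C	-0.97	0.09	0.12	0.04
Lys_CTT_48	m5C	-0.97	-0.12	0.16	0.04
Ile_AAT_GAT_48	m5C	-0.96	0.03	0.27	0.05
Thr_TGT1_CGT2_48	m5C	-0.95	-0.23	0.07	0.00
Leu_TAA_48	m5C	-0.94	0.17	0.11	-0.03
Ser_GCT_49	m5C	-0.94	0.18	0.09	0.02
Phe_GAA_49	m5C	-0.94	-0.08	0.11	-0.28
Trp_CCA_39	Nm	-0.91	0.29	0.02	-0.13
Arg_ACG_16	D	-0.90	0.38	-0.09	0.00
Gly_CCC2_20	D	-0.89	-0.27	0.14	0.06
Lys_CTT_54	Nm	-0.86	0.15	-0.08	-0.31
Ser_AGA_TGA_18	Nm	-0.85	-0.15	-0.49	-0.05
Ser_AGA_TGA_44	Nm	-0.84	-0.24	-0.41	0.06
Ser_GCT_44	Nm	-0.81	-0.35	-0.42	0.09
Lys_TTT_54	Nm	-0.80	0.39	-0.14	-0.19
Ser_GCT_18	Nm	-0.79	0.32	-0.14	-0.38
Lys_TTT_16	D	-0.75	0.57	-0.17	0.12
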