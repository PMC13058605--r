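group_min	time_h	c_m_mean	c_m_sd	c_eq_mean	c_eq_sd
0	3	0.25	0.05	0.20	0.04
0	6	1.55	0.13	1.22	0.10
0	27	2.00	0.19	1.58	0.15
5	3	0.36	0.06	0.28	0.05
5	6	1.29	0.18	1.02	0.15
5	27	1.79	0.21	1.42	0.17
10	3	0.23	0.02	0.17	0.02
10	6	1.30	0.13	1.03	0.13
10	27	2.29	0.23	1.81	0.19
20	3	0.91	0.03	0.72	0.02
20	6	1.38	0.19	1.08	0.15
20	27	2.31	0.21	1.83	0.17
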