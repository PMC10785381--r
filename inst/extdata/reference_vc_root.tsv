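trait	model	g	l	r	s1	s2	s3	e	h2_t1	H2_t1	h2_t2	H2_t2	h2_t3	H2_t3	gcv
TRL	RM1	10.13	2.6e-7	127.82	61.89	88.45	232.72	50.00	0.04	0.04	0.04	0.04	0.02	0.02	9.4
TRL	RM2	8.86	9.5e-7	193.46	95.16	53.37	238.64	60.82	0.03	0.03	0.03	0.03	0.02	0.02	8.8
SRL	RM1	4.02	6.5e-7	109.82	16.76	1.93	26.42	19.00	0.03	0.03	0.03	0.03	0.03	0.03	10.2
SRL	RM2	4.23	1.1e-7	110.64	29.55	2.15	66.19	19.67	0.03	0.03	0.03	0.03	0.02	0.02	10.4
DRL	RM1	0.69	4.2e-8	34.46	6.30	29.88	67.70	19.06	0.01	0.01	0.01	0.01	0.01	0.01	6.5
DRL	RM2	0.36	8.6e-8	40.25	1.70	44.11	159.85	24.07	0.005	0.005	0.003	0.003	0.002	0.002	4.7
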