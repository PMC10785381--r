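trait	model	g	l	ng	nl	r	tg	tl	s1	s2	e	h2	H2	gcv
GY	AM1	0.23	0.11	3.7e-7	2.5e-7	0.13	0.01	0.01	0.12	0.06	0.48	0.22	0.32	6.8
GY	AM2	0.24	0.09	9.9e-4	2.6e-7	0.14	0.01	0.01	0.15	0.04	0.50	0.22	0.31	7.0
GPC	AM1	0.09	0.01	2.6e-8	1.4e-7	0.03	3.5e-3	1.8e-3	0.26	0.16	0.04	0.24	0.27	3.2
GPC	AM2	0.10	0.01	3.1e-8	1.0e-7	0.10	2.6e-3	4.3e-3	0.45	0.18	0.05	0.19	0.20	3.4
GNR	AM1	50.1	12.6	1.1e-6	0.65	34.3	3.9e-6	5.32	89.6	43.9	112.2	0.18	0.23	6.6
GNR	AM2	55.7	7.24	0.20	1.24	48.8	0.02	8.27	111.8	40.4	118.7	0.18	0.20	7.0
TKW	AM1	8.97	4.49	9.7e-3	6.0e-8	0.55	0.01	3.0e-10	0.44	1.41	2.62	0.52	0.78	5.7
TKW	AM2	8.66	4.79	5.2e-10	2.0e-10	0.67	0.01	7.3e-10	0.20	1.23	3.02	0.49	0.76	5.6
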