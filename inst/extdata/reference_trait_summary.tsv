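trait	n	min	mean	max	sd	cv
GY	1031	3.52	7.07	10.33	1.08	15.28
GPC	1031	7.34	9.42	11.70	0.76	8.07
GNR	1031	51.06	106.55	165.16	18.36	17.23
TKW	1031	38.39	52.83	68.28	4.44	8.41
TRL	748	1.98	33.83	108.41	20.96	61.96
SRL	771	0	19.68	61.40	13.83	70.27
DRL	762	0	12.85	55.07	10.91	84.90
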