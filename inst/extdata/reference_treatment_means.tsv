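treatment	GY	GPC	GNR	TKW
wet	7.20	9.30	107.02	53.42
dry	6.91	9.59	106.72	52.40
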