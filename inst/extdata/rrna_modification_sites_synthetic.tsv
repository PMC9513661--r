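position	molecule	modification
367	12S	m5U
776	12S	m4C
778	12S	m5C
936	12S	m62A
937	12S	m62A
1488	16S	Psi
2059	16S	Gm
2173	16S	Psi
2229	16S	Um
2481	16S	m1A
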