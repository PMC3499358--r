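virus	natural_host	trait	n_flies	n_lines	v_e	v_g	h2	cvg
DCV	D. melanogaster	survival	14415	185	1.15	0.61	0.34	20
FHV	beetle	survival	12660	182	2.10	0.17	0.07	7
DMelSV	D. melanogaster	co2_sensitivity	11541	185	4.79	1.94	0.29	NA
DAffSV	D. affinis	co2_sensitivity	8604	181	3.88	0.61	0.13	NA
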