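locus	site_id	virus	n_resistant_lines	n_typed_lines	frac_h2
pastrel	3L:7350895	DCV	21	142	0.47
ref2P	2L:ref2P	DMelSV	NA	NA	0.08
CHKov1_doc	3R:CHKov1	DMelSV	NA	NA	0.29
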