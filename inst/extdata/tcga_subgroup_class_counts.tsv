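subgroup	level	n
purple	Immunoreactive	38
purple	Other	12
purple	NA	5
yellow	Immunoreactive	59
yellow	Other	184
yellow	NA	9
green	Immunoreactive	7
green	Other	141
green	NA	9
orange	Immunoreactive	0
orange	Other	37
orange	NA	2
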