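subgroup	level	n
purple	proliferative	5
purple	other	45
purple	NA	5
orange	proliferative	31
orange	other	6
orange	NA	2
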