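design	guide	protospacer
A-B	sgRNA1	GGTGCCGTCGAGAAGCGCCA
A-B	sgRNA2	GAGACGTTGAGAATGTCGCA
A-D	sgRNA1	GCCCTTCACTGGTTGAGTTG
A-D	sgRNA2	GTAGAAAGGGCTTTGACACG
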