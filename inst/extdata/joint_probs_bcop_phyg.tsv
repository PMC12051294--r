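#chrom_a	X	C	B	A
X	0.253	0.002	0.002	0.003
II	0.000	0.166	0.001	0.003
III	0.002	0.001	0.241	0.004
IV	0.002	0.002	0.002	0.315
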