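#locus_1	locus_2	n_subzones	observed_mb
Centromere	FBR1	2	3.49
5' X' breakpoint	FBR1	0.5	0.620
FBR1	FBR2	7	10.3
FBR2	FBR3	26	42.7
FBR3	3' X' breakpoint	3	4.65
FBR3	3' end of chromosome	6	12.3
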