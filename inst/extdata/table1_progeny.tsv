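genotype	normal	hs_exceptional	other	recombinant	paternal_ndj	decimals
C1_mono	182	1	0	0	0	0
C4_mono	1136	0	6	0	6	0
In1_C4	626	9	1	1	0	1
FM7_C4	1232	25	0	0	0	1
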