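genotype	normal	hs_exceptional	other	recombinant	paternal_ndj	decimals
XXY_yw	2076	40	0	0	0	1
FM7_XXY	1356	1077	0	0	0	1
In1_XXY	1426	1371	28	25	3	1
C1C4	0	600	18	0	0	1
C2L_C2R	0	2479	26	0	0	1
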