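genotype	stage	single_mass	one_plus_out	compound_out	hs_config	other_config	hs_recoverable
XXY_yw	metaphase_4d	54	0	0	2	0	2
FM7_XXY	metaphase_4d	52	0	0	33	0	33
In1_XXY	metaphase_4d	83	0	0	56	0	56
C1C4	metaphase_4d	68	0	0	65	3	65
C2L_C2R	metaphase_4d	46	0	0	45	1	45
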