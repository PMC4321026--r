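genotype	stage	single_mass	one_plus_out	compound_out	hs_config	other_config	hs_recoverable
C1_mono	prometaphase_2d	32	40	23	0	0	0
C1_mono	metaphase_4d	112	9	0	2	0	2
C2EN_mono	prometaphase_2d	29	60	28	0	0	0
C2EN_mono	metaphase_4d	57	8	0	2	0	2
C4_mono	prometaphase_2d	72	2	2	0	0	0
C4_mono	metaphase_4d	60	0	0	2	0	0
In1_C4	prometaphase_2d	54	7	7	0	0	0
In1_C4	metaphase_4d	78	2	0	5	0	5
FM7_C4	prometaphase_2d	60	8	8	0	0	0
FM7_C4	metaphase_4d	70	2	0	5	0	5
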