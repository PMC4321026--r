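class	count	partition
ywf_Y_male	696	hs_exceptional
In1_yw_yY_female	675	hs_exceptional
yw_yY_male	367	normal
In1_yY_male	350	normal
yw_ywf_female	352	normal
In1_ywf_female	357	normal
recombinant	25	other
paternal_ndj	3	other
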