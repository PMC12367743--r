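variable	tc_positive	tc_n	brt_positive	brt_n
ssa_ro52_positive	2	6	0	7
heliotrope_rash	4	7	2	7
sex_male	1	7	2	7
arthritis	2	7	2	7
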