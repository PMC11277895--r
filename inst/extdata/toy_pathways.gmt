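PATHWAY_A	toy set A	EXP_G0001	EXP_G0002	EXP_G0003	MET_G0001
PATHWAY_B	toy set B	MUT_G0001	MUT_G0002	CNV_G0001	CNV_G0002	CNV_G0003
PATHWAY_C	toy set C	EXP_G0004	EXP_G0005	EXP_G0006	EXP_G0007	EXP_G0008	EXP_G0009
PATHWAY_D	toy set D	MET_G0002	MET_G0003
PATHWAY_E	toy set E	MUT_G0003	EXP_G0010	CNV_G0004	MET_G0004	MET_G0005
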