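fine_id	fine_name	level_a	level_b	level_c
1	cortex_L	CerebralCortex_L	Frontal_L	none
2	cortex_R	CerebralCortex_R	Frontal_R	none
3	white_L	WhiteMatter_L	AnteriorWM_L	none
4	white_R	WhiteMatter_R	AnteriorWM_R	none
5	lateral_ventricle_L	none	none	Lateral Ventrical_body_L
6	lateral_ventricle_R	none	none	Lateral Ventrical_body_R
7	third_ventricle	none	none	III_and_IV_ventricle
8	hippocampus_L	CerebralCortex_L	Limbic_L	Hippocampus_L
9	hippocampus_R	CerebralCortex_R	Limbic_R	Hippocampu_R
10	csf_shell	none	none	none
11	skull_base	none	none	none
12	skin	none	none	none
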