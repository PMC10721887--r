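variant_id	gene	chrom	pos	ref	alt	consequence	revel	sift	polyphen2_hdiv	polyphen2_hvar	lrt	mutation_taster	clinvar_assertion	clinvar_n_submitters	clinvar_conflict_flag	varsome_assertion	af_gnomad_EUR	expected_M1	expected_M2	expected_M3
v_plof_clean	PKD1	16	0	C	T	stop_gained	NA	missing	missing	missing	missing	missing	none	0	FALSE	none	1e-06	TRUE	TRUE	TRUE
v_splice_ess	PKD2	4	0	C	T	splice_donor_variant	NA	missing	missing	missing	missing	missing	none	0	FALSE	none	1e-06	TRUE	TRUE	TRUE
v_splice_region	PKD1	16	0	C	T	splice_region_variant	0.3	tolerated	tolerated	tolerated	tolerated	tolerated	none	0	FALSE	none	1e-06	FALSE	FALSE	FALSE
v_plof_varsome_lb	COL4A3	2	0	C	T	frameshift_variant	NA	missing	missing	missing	missing	missing	none	0	FALSE	LB	1e-06	FALSE	FALSE	FALSE
v_plof_clinvar_lb	COL4A4	2	0	C	T	stop_lost	NA	missing	missing	missing	missing	missing	LB	1	FALSE	none	1e-06	FALSE	FALSE	FALSE
v_p_two_sub	PKD1	16	0	C	T	missense_variant	0.2	tolerated	tolerated	tolerated	tolerated	tolerated	P	2	FALSE	VUS	1e-06	TRUE	TRUE	FALSE
v_p_single_sub	PKD1	16	0	C	T	missense_variant	0.95	damaging	damaging	damaging	damaging	damaging	P	1	FALSE	none	1e-06	FALSE	FALSE	TRUE
v_p_conflict	PKD2	4	0	C	T	missense_variant	0.2	tolerated	tolerated	tolerated	tolerated	tolerated	P	3	TRUE	none	1e-06	FALSE	FALSE	FALSE
v_lp_two_sub	COL4A3	2	0	C	T	missense_variant	0.2	tolerated	tolerated	tolerated	tolerated	tolerated	LP	3	FALSE	none	1e-06	FALSE	TRUE	FALSE
v_dmis_clean	COL4A5	X	0	C	T	missense_variant	0.85	damaging	damaging	damaging	damaging	damaging	none	0	FALSE	VUS	1e-06	FALSE	FALSE	TRUE
v_dmis_blb	COL4A3	2	0	C	T	missense_variant	0.9	damaging	damaging	damaging	damaging	damaging	B	2	FALSE	none	1e-06	FALSE	FALSE	FALSE
v_dmis_4of5	PKD1	16	0	C	T	missense_variant	0.9	damaging	damaging	damaging	damaging	tolerated	none	0	FALSE	none	1e-06	FALSE	FALSE	FALSE
v_revel_boundary	COL4A4	2	0	C	T	missense_variant	0.7	damaging	damaging	damaging	damaging	damaging	none	0	FALSE	none	1e-06	FALSE	FALSE	FALSE
v_revel_missing	PKD2	4	0	C	T	missense_variant	NA	damaging	damaging	damaging	damaging	damaging	none	0	FALSE	none	1e-06	FALSE	FALSE	FALSE
v_p_and_plof	COL4A5	X	0	C	T	stop_gained	NA	missing	missing	missing	missing	missing	P	4	FALSE	none	1e-06	TRUE	TRUE	TRUE
v_dmis_and_p	COL4A3	2	0	C	T	missense_variant	0.8	damaging	damaging	damaging	damaging	damaging	P	2	FALSE	none	1e-06	TRUE	TRUE	TRUE
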