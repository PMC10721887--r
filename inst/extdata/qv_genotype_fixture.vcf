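##fileformat=VCFv4.2
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
##FORMAT=<ID=GQ,Number=1,Type=Integer,Description="Genotype quality">
##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	S_HET_F	S_COMPHET_F	S_HOM_F	S_HEMI_M	S_XHET_M	S_MASKED_F	S_REF_F
16	1000	v_plof_clean	C	T	.	PASS	GENE=PKD1	GT:GQ:DP	0/1:97:30	0/0:97:30	0/0:97:30	0/0:97:30	0/0:97:30	0/1:90:30	0/0:97:30
4	2000	v_splice_ess	C	T	.	PASS	GENE=PKD2	GT:GQ:DP	0/0:97:30	0/0:97:30	0/0:97:30	0/0:97:30	0/0:97:30	0/0:97:30	0/0:97:30
16	3000	v_splice_region	C	T	.	PASS	GENE=PKD1	GT:GQ:DP	0/0:97:30	0/0:97:30	0/0:97:30	0/0:97:30	0/0:97:30	0/0:97:30	0/0:97:30
2	4000	v_plof_varsome_lb	C	T	.	PASS	GENE=COL4A3	GT:GQ:DP	0/0:97:30	0/0:97:30	0/0:97:30	0/0:97:30	0/0:97:30	0/0:97:30	0/0:97:30
2	5000	v_plof_clinvar_lb	C	T	.	PASS	GENE=COL4A4	GT:GQ:DP	0/0:97:30	0/0:97:30	0/0:97:30	0/0:97:30	0/0:97:30	0/0:97:30	0/0:97:30
16	6000	v_p_two_sub	C	T	.	PASS	GENE=PKD1	GT:GQ:DP	0/0:97:30	0/0:97:30	0/0:97:30	0/0:97:30	0/0:97:30	0/0:97:30	0/0:97:30
16	7000	v_p_single_sub	C	T	.	PASS	GENE=PKD1	GT:GQ:DP	0/0:97:30	0/0:97:30	0/0:97:30	0/0:97:30	0/0:97:30	0/0:97:30	0/0:97:30
4	8000	v_p_conflict	C	T	.	PASS	GENE=PKD2	GT:GQ:DP	0/0:97:30	0/0:97:30	0/0:97:30	0/0:97:30	0/0:97:30	0/0:97:30	0/0:97:30
2	9000	v_lp_two_sub	C	T	.	PASS	GENE=COL4A3	GT:GQ:DP	0/0:97:30	0/1:97:30	0/0:97:30	0/0:97:30	0/0:97:30	0/0:97:30	0/0:97:30
X	10000	v_dmis_clean	C	T	.	PASS	GENE=COL4A5	GT:GQ:DP	0/0:97:30	0/0:97:30	0/0:97:30	0/0:97:30	0/1:97:30	0/0:97:30	0/0:97:30
2	11000	v_dmis_blb	C	T	.	PASS	GENE=COL4A3	GT:GQ:DP	0/0:97:30	0/0:97:30	0/0:97:30	0/0:97:30	0/0:97:30	0/0:97:30	0/0:97:30
16	12000	v_dmis_4of5	C	T	.	PASS	GENE=PKD1	GT:GQ:DP	0/0:97:30	0/0:97:30	0/0:97:30	0/0:97:30	0/0:97:30	0/0:97:30	0/0:97:30
2	13000	v_revel_boundary	C	T	.	PASS	GENE=COL4A4	GT:GQ:DP	0/0:97:30	0/0:97:30	0/0:97:30	0/0:97:30	0/0:97:30	0/0:97:30	0/0:97:30
4	14000	v_revel_missing	C	T	.	PASS	GENE=PKD2	GT:GQ:DP	0/0:97:30	0/0:97:30	0/0:97:30	0/0:97:30	0/0:97:30	0/0:97:30	0/0:97:30
X	15000	v_p_and_plof	C	T	.	PASS	GENE=COL4A5	GT:GQ:DP	0/0:97:30	0/0:97:30	0/0:97:30	1/1:97:30	0/0:97:30	0/0:97:30	0/0:97:30
2	16000	v_dmis_and_p	C	T	.	PASS	GENE=COL4A3	GT:GQ:DP	0/0:97:30	0/1:97:30	1/1:97:30	0/0:97:30	0/0:97:30	0/0:97:30	0/0:97:30
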