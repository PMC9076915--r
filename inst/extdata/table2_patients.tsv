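patient_id	histology	regimen	nri	rcb	grade	t_stage	n_stage	subtype	recurrence	vital_status	exome_seq	rna_seq	dna_pre_tp	dna_post_tp	rna_pre_tp	rna_post_tp
s97	IDC	6x ddAC	0.33	2	NA	2	neg	LUM	0	A	1	1	70	80	70	75
s188	IDC	1x AC + 1x CD	0	2	3	2	neg	TN	1	D	1	0	80	80	NA	NA
s2046	IDC	6x ddAC	0	3	3	2	pos	TN	1	D	1	1	70	70	50	70
s2271	IDC	6x ddAC	0.33	2	3	2	pos	TN	1	D	1	1	80	55	90	55
s2472	IDC	4x ddAC + 2x CTC+PSCT	0.33	3	2	2	pos	TN	1	D	0	1	NA	NA	80	70
s2492	IDC	6x ddAC	0.33	3	2	2	pos	TN	1	D	1	1	90	50	60	50
s2653	IDC	3x ddAC + 2x CD + 2x D	0	2	2	2	pos	LUM	1	A	0	1	NA	NA	60	50
s2661	Papillary carcinoma	6x ddAC	0.2	NA	1	4	neg	LUM	0	A	1	1	90	80	90	80
s2677	ILC	6x ddAC	0	NA	2	2	neg	LUM	0	A	1	1	50	70	50	70
s2691	IDC	6x ddAC	0.33	3	2	2	pos	LUM	0	A	1	1	40	60	40	60
s2739	IDC	3x AC + 3x CD	0.33	2	2	2	pos	LUM	0	A	1	1	80	60	80	60
s2789	IDC	6x ddAC	0.33	2	2	2	neg	LUM	0	A	1	1	60	40	60	40
s2817	IDC	3x AC + 3x CD	0	3	2	2	pos	LUM	0	A	1	1	70	80	70	80
s2852	IDC	3x ddAC	0	3	2	2	pos	LUM	1	A	1	1	70	60	70	60
s2976	IDC	3x ddAC + 4x paclitaxel	0	2	2	2	neg	LUM	0	A	1	1	70	50	70	50
s3001	IDC	6x ddAC	0	3	2	2	pos	LUM	0	A	1	1	60	65	60	65
s3036	IDC	6x ddAC	0.25	2	1	3	pos	LUM	0	A	1	1	50	50	50	50
s3065	IDC	6x ddAC	0	2	2	2	pos	LUM	0	A	1	1	70	60	70	60
s3067	ILC	6x ddAC	0	3	2	1	pos	LUM	0	A	1	1	60	60	60	60
s3130	IDC	6x ddAC	0	3	2	1	pos	LUM	0	A	1	1	60	55	60	55
s3161	IDC	3x ddAC + 9x paclitaxel	0	3	2	2	pos	LUM	0	A	1	1	60	80	60	80
s3280	Metaplastic	3x ddAC + 3x carbo/paclitaxel	NA	NA	3	2	pos	TN	0	A	1	0	60	60	NA	NA
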