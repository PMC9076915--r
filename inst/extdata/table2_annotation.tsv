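sample_id	patient_id	subtype	timepoint	nri	pcr	rfs_time	rfs_event	purity
s97_pre	s97	ERpos	pre	0.33	no	NA	NA	0.7
s97_post	s97	ERpos	post	0.33	no	NA	NA	0.8
s188_pre	s188	TN	pre	0	no	NA	NA	0.8
s188_post	s188	TN	post	0	no	NA	NA	0.8
s2046_pre	s2046	TN	pre	0	no	NA	NA	0.7
s2046_post	s2046	TN	post	0	no	NA	NA	0.7
s2271_pre	s2271	TN	pre	0.33	no	NA	NA	0.8
s2271_post	s2271	TN	post	0.33	no	NA	NA	0.55
s2472_pre	s2472	TN	pre	0.33	no	NA	NA	0.8
s2472_post	s2472	TN	post	0.33	no	NA	NA	0.7
s2492_pre	s2492	TN	pre	0.33	no	NA	NA	0.9
s2492_post	s2492	TN	post	0.33	no	NA	NA	0.5
s2653_pre	s2653	ERpos	pre	0	no	NA	NA	0.6
s2653_post	s2653	ERpos	post	0	no	NA	NA	0.5
s2661_pre	s2661	ERpos	pre	0.2	no	NA	NA	0.9
s2661_post	s2661	ERpos	post	0.2	no	NA	NA	0.8
s2677_pre	s2677	ERpos	pre	0	no	NA	NA	0.5
s2677_post	s2677	ERpos	post	0	no	NA	NA	0.7
s2691_pre	s2691	ERpos	pre	0.33	no	NA	NA	0.4
s2691_post	s2691	ERpos	post	0.33	no	NA	NA	0.6
s2739_pre	s2739	ERpos	pre	0.33	no	NA	NA	0.8
s2739_post	s2739	ERpos	post	0.33	no	NA	NA	0.6
s2789_pre	s2789	ERpos	pre	0.33	no	NA	NA	0.6
s2789_post	s2789	ERpos	post	0.33	no	NA	NA	0.4
s2817_pre	s2817	ERpos	pre	0	no	NA	NA	0.7
s2817_post	s2817	ERpos	post	0	no	NA	NA	0.8
s2852_pre	s2852	ERpos	pre	0	no	NA	NA	0.7
s2852_post	s2852	ERpos	post	0	no	NA	NA	0.6
s2976_pre	s2976	ERpos	pre	0	no	NA	NA	0.7
s2976_post	s2976	ERpos	post	0	no	NA	NA	0.5
s3001_pre	s3001	ERpos	pre	0	no	NA	NA	0.6
s3001_post	s3001	ERpos	post	0	no	NA	NA	0.65
s3036_pre	s3036	ERpos	pre	0.25	no	NA	NA	0.5
s3036_post	s3036	ERpos	post	0.25	no	NA	NA	0.5
s3065_pre	s3065	ERpos	pre	0	no	NA	NA	0.7
s3065_post	s3065	ERpos	post	0	no	NA	NA	0.6
s3067_pre	s3067	ERpos	pre	0	no	NA	NA	0.6
s3067_post	s3067	ERpos	post	0	no	NA	NA	0.6
s3130_pre	s3130	ERpos	pre	0	no	NA	NA	0.6
s3130_post	s3130	ERpos	post	0	no	NA	NA	0.55
s3161_pre	s3161	ERpos	pre	0	no	NA	NA	0.6
s3161_post	s3161	ERpos	post	0	no	NA	NA	0.8
s3280_pre	s3280	TN	pre	NA	no	NA	NA	0.6
s3280_post	s3280	TN	post	NA	no	NA	NA	0.6
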