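mag	n_cds	n_low_pi	n_low_dnds	n_relaxed_dnds	n_no_dnds	longest_run	fst_regions_1sd	fst_regions_2sd
NORP83	2657	60	4	9	43	4	8	0
NORP139	1538	32	6	12	10	1	0	0
NORP147	2650	0	0	0	0	0	0	0
NORP163	2182	190	37	11	117	5	14	1
NORP169	2842	238	19	19	175	3	3	0
NORP246	3851	22	5	3	12	2	0	0
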