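mag	TP0	TP1	TP2	TP3	TP4	TP5	TP6	TP7	TP8	TP9
NORP83	0.02	16.62	0.23	13.69	11.27	2.73	9.95	1.04	0.38	0.00
NORP139	2.13	6.84	6.90	4.37	9.78	8.50	6.97	1.27	1.21	0.01
NORP147	0.00	36.41	0.08	20.33	12.36	0.11	0.30	0.02	0.02	0.03
NORP163	20.86	16.51	48.66	3.43	2.92	1.12	0.24	19.77	20.95	2.97
NORP169	2.12	6.53	5.09	0.82	0.52	1.43	8.38	4.84	4.14	0.08
NORP246	0.02	11.60	0.10	8.34	5.24	1.74	0.12	0.10	0.13	0.00
NORP6	0.00	0.00	0.00	0.00	88.61	0.00	0.02	0.00	0.00	0.00
NORP57	0.04	0.00	0.00	0.00	0.00	0.00	0.00	0.00	0.00	38.25
NORP100	1.05	0.10	1.97	0.08	0.16	0.11	0.01	2.46	2.77	38.98
NORP167	0.03	30.13	0.07	0.13	0.01	0.00	0.00	0.01	0.00	0.00
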