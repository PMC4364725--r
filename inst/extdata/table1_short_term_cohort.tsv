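sample_id	age_years	diagnosis	sex	igf1_baseline	igf1_baseline_centile	igfbp3_baseline	igfbp3_baseline_centile	igf1_stimulated	igfbp3_stimulated	knemometry_rate
P1	13.00	NSD	m	126	2	2.23	6	200	3.49	0.1
P2	11.58	SGA	f	232	24	3.29	45	243	3.4	0.75
P3	13.33	NSD	m	88	<0.1	1.97	1	144	2.98	0.4
P4	8.92	STH-D~	f	82	2	2.37	27	170	2.74	-0.1
P7	7.92	Q-STH-D	m	77	4	1.22	<0.1	170	1.38	0.5
P8	7.67	SGA	m	229	86	3.5	93	332	2.1	4.1
P9	12.33	Q-STH-D	m	180	18	2.43	12	287	3.53	0.9
P10	10.67	NSD	m	118	5	1.8	2	227	2.47	1
P11	7.33	STH-D	m	46	0.4	1.58	2.6	72	2.53	0.55
P12	9.42	SGA	m	212	76	3.95	94	442	4.39	1.3
P13	8.67	NSD	f	133	18	2.34	25	222	2.78	0.2
P14	15.42	STH-D	m	160	0.2	3.27	42.1	283	3.87	1.1
P15	12.92	NSD	f	172	2.2	3.14	37.9	156	3.71	0
P16	6.00	SGA	m	69	16.5	2.66	64.1	139	2.85	1.2
P17	11.58	NSD	f	171	9.6	3.35	53.3	338	3.5	0.75
P18	6.42	IGF1-D	f	82	22.3	1.75	7.7	71	1.67	0.3
P19	6.17	SGA	m	58	9	1.14	0.1	64	2.82	-0.5
P20	13.33	STH-D, PAN	m	67	0	1.6	0.1	286	4.39	0.6
P21	11.75	STH-D	f	202	16.5	3.03	34.4	321	3.14	0
P22	5.17	SGA	m	37	1.1	1.69	9.8	62	2.44	0.3
P23	6.92	SGA, TS	f	192	85.5	1.85	11.6	343	4.66	1.1
P24	13.17	STH-D	m	198	29.4	2.77	27.2	288	1.89	0.5
P25	8.00	STH-D, SGA	f	100	15.2	2.76	52.5	105	2.44	0.2
P26	5.83	UTS	f	121	59.3	3.02	83	233	4.04	0.1
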