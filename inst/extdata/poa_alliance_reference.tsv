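clade	n_min	n_max	n_seq	pi	var_pi	age20	dr20_min	dr20_max	age25	ci_low	ci_high	dr25_min	dr25_max
Alopecurus/Dupontia	10	46	32	0.0168	0.000076	1.45	1.11	2.17	1.81	1.52	2.12	0.89	1.74
Apera/Bellardiochloa	8	18	12	0.0186	0.000105	0.51	2.70	4.28	0.64	0.54	0.75	2.16	3.43
Arctagrostis	9	9	22	0.0122	0.000044	0.98	1.54	1.54	1.22	1.03	1.43	1.23	1.23
Beckmannia	3	3	6	0.0132	0.000068	0.23	1.73	1.73	0.29	0.25	0.34	1.39	1.39
Catabrosa/Paracolpodium	7	14	13	0.0353	0.000350	0.56	2.24	3.47	0.70	0.59	0.82	1.79	2.78
Cinna	4	4	7	0.0087	0.000030	0.28	2.48	2.48	0.35	0.30	0.41	1.98	1.98
Milium	3	5	6	0.0379	0.000507	0.24	1.71	3.87	0.29	0.25	0.34	1.38	3.12
Phippsia	3	4	5	0.0097	0.000043	0.19	2.17	3.72	0.23	0.20	0.28	1.74	2.97
Phleum	4	16	5	0.0279	0.000309	0.19	3.70	11.10	0.23	0.20	0.27	2.97	8.90
Poa I	4	12	11	0.0336	0.000330	0.47	1.49	3.84	0.58	0.49	0.68	1.19	3.07
Poa II	6	18	9	0.0077	0.000022	0.37	2.95	5.89	0.47	0.39	0.55	2.36	4.71
Poa III	7	21	12	0.0102	0.000035	0.51	2.45	4.59	0.64	0.54	0.75	1.96	3.67
Poa IV	13	38	14	0.0025	0.000003	0.61	3.09	4.86	0.76	0.64	0.89	2.47	3.89
Poa V	25	74	34	0.0079	0.000019	1.54	1.64	2.35	1.92	1.62	2.26	1.31	1.88
Poa VI	5	15	6	0.0039	0.000008	0.23	3.93	8.64	0.29	0.25	0.34	3.14	6.92
Poa VII	9	27	16	0.0167	0.000082	0.70	2.15	3.72	0.87	0.74	1.02	1.72	2.98
Poa VIII	34	101	45	0.0007	0.000000	2.05	1.38	1.91	2.56	2.16	3.01	1.11	1.53
Puccinellia	21	107	40	0.0081	0.000020	1.82	1.29	2.19	2.27	1.92	2.67	1.03	1.75
Zingeria/Colpodium	8	12	27	0.0199	0.000107	1.21	1.14	1.48	1.52	1.28	1.78	0.91	1.18
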