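property	accession	A	C	D	E	F	G	H	I	K	L	M	N	P	Q	R	S	T	V	W	Y	X
hydrophobicity	KYTJ820101	1.8	2.5	-3.5	-3.5	2.8	-0.4	-3.2	4.5	-3.9	3.8	1.9	-3.5	-1.6	-3.5	-4.5	-0.8	-0.7	4.2	-0.9	-1.3	0
solvent	JANJ780101	27.8	15.5	60.6	68.2	25.5	24.5	50.7	22.8	103.0	27.6	33.5	60.1	51.5	68.7	94.7	42.0	45.0	23.7	34.7	55.2	0
polarity	GRAR740102	8.1	5.5	13.0	12.3	5.2	9.0	10.4	5.2	11.3	4.9	5.7	11.6	8.0	10.5	10.5	9.2	8.6	5.9	5.4	6.2	0
polarizability	CHAM820101	0.046	0.128	0.105	0.151	0.290	0.000	0.230	0.186	0.219	0.186	0.221	0.134	0.131	0.180	0.291	0.062	0.108	0.140	0.409	0.298	0
accessible	CHOC760101	115	135	150	190	210	75	195	175	200	170	185	160	145	180	225	115	140	155	255	230	0
pK_N	FASG760104	9.69	8.35	9.60	9.67	9.18	9.78	9.17	9.68	9.18	9.60	9.21	8.80	10.64	9.13	8.99	9.21	9.10	9.62	9.44	9.11	0
pK_C	FASG760105	2.34	1.92	1.88	2.10	2.16	2.35	1.82	2.36	2.16	2.36	2.28	2.02	1.95	2.17	1.82	2.19	2.09	2.32	2.43	2.20	0
melting_point	FASG760102	297	178	270	249	284	290	277	284	224	337	283	236	222	185	238	228	253	293	282	344	0
molecular_weight	FASG760101	89.09	121.15	133.10	147.13	165.19	75.07	155.16	131.17	146.19	131.17	149.21	132.12	115.13	146.15	174.20	105.09	119.12	117.15	204.24	181.19	0
optical_rotation	FASG760103	1.80	-16.50	5.05	12.00	-34.50	0.00	-38.50	12.40	14.60	-11.00	-10.00	-5.60	-86.20	6.30	12.50	-7.50	-28.00	5.63	-33.70	-10.00	0
net_charge	KLEP840101	0	0	-1	-1	0	0	0	0	1	0	0	0	0	0	1	0	0	0	0	0	0
entropy_formation	HUTJ700103	154.33	219.79	194.91	223.16	204.74	127.90	242.54	233.21	300.46	232.30	202.65	207.90	179.93	235.51	341.01	174.06	205.80	207.60	237.01	229.15	0
heat_capacity	HUTJ700101	29.22	50.70	37.09	41.84	48.52	23.71	59.64	45.00	57.10	48.03	69.32	38.30	36.13	44.02	26.37	32.40	35.20	40.35	56.92	51.73	0
absolute_entropy	HUTJ700102	30.88	53.83	40.66	44.98	51.06	24.74	65.99	49.71	63.21	50.62	55.32	41.70	39.21	46.62	68.43	35.65	36.50	42.75	60.00	51.15	0
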