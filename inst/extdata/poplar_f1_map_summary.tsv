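group	snp_maternal	anchored_maternal	length_maternal_cM	snp_paternal	anchored_paternal	length_paternal_cM	chrom_size_Mb
LG01	240	196	471.20	155	121	512.67	50.50
LG02	162	133	328.55	119	98	327.69	25.26
LG03	134	113	279.22	94	74	290.22	21.82
LG04	120	87	254.00	80	60	203.88	24.27
LG05	112	92	225.29	86	71	261.80	25.89
LG06	130	109	303.32	106	88	339.89	27.91
LG07	81	69	186.87	70	57	176.52	15.61
LG08	141	125	242.47	107	88	268.86	19.47
LG09	90	77	165.32	82	68	189.55	12.95
LG10	145	119	249.87	89	75	265.25	22.58
LG11	85	70	172.13	45	32	155.20	18.50
LG12	75	61	150.29	46	37	163.38	15.76
LG13	85	71	167.25	64	60	184.52	16.32
LG14	102	83	176.57	74	60	219.07	18.92
LG15	73	62	151.34	48	44	162.67	15.28
LG16	72	61	155.82	30	24	118.28	14.49
LG17	59	47	135.89	64	49	197.88	16.08
LG18	61	47	144.89	36	29	158.74	16.96
LG19	45	32	106.87	35	22	159.97	15.94
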