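name	herb	mw	alogp	hbd	hba	ob	dl	flags
DFV ((2S)-7-hydroxy-2-(4-hydroxyphenyl)chroman-4-one)	HE	256.27	2.57	2	4	32.76	0.18	menopause
Delta7-dehydrosophoramine	CPC	242.35	1.09	0	3	54.45	0.25	
Alizarin-2-methylether	RMO	254.25	2.53	1	4	32.81	0.21	
1-Hydroxy-3-methoxy-9,10-anthraquinone	RMO	254.25	2.53	1	4	104.33	0.21	
1-Hydroxy-6-hydroxymethylanthracenequinone	RMO	254.25	1.94	2	4	81.77	0.21	
Skimmianin (4,7,8-trimethoxyfuro[2,3-b]quinoline)	CPC	259.28	2.33	0	5	40.14	0.20	
Magnograndiolide	HE/CPC	266.37	1.18	2	4	63.71	0.19	
Coumaroyltyramine (cis-N-p-Coumaroyltyramine)	RA	283.35	2.88	3	4	112.9	0.20	
Kaempferol (3,5,7-trihydroxy-2-(4-hydroxyphenyl)chromen-4-one)	HE/RA	286.25	1.77	4	6	41.88	0.24	menopause
Luteolin (2-(3,4-dihydroxyphenyl)-5,7-dihydroxychromen-4-one)	HE	286.25	2.07	4	6	36.16	0.25	menopause
Rutaecarpine	CPC	287.34	3.36	1	3	40.30	0.60	menopause
8-(3-methylbut-2-enyl)-2-phenyl-chromone	HE	290.38	4.99	0	2	48.54	0.25	
Dehydrotanshinone II A	CPC	292.35	4.22	0	3	43.76	0.40	
Chryseriol (5,7-dihydroxy-2-(4-hydroxy-3-methoxyphenyl)chromen-4-one)	HE	300.28	2.32	3	6	35.85	0.27	menopause
Phellopterin	CPC	300.33	3.64	0	5	40.19	0.28	menopause
Cnidilin	RAS	300.33	3.64	0	5	32.69	0.28	menopause
Quercetin (2-(3,4-dihydroxyphenyl)-3,5,7-trihydroxychromen-4-one)	HE	302.25	1.50	5	7	46.43	0.28	menopause
(Z)-3-(4-hydroxy-3-methoxy-phenyl)-N-[2-(4-hydroxyphenyl)ethyl]acrylamide	RA	313.38	2.86	3	5	118.35	0.26	
1,6-dihydroxy-5-methoxy-2-(methoxymethyl)-9,10-anthraquinone	RMO	314.31	2.06	2	6	104.54	0.34	
Hippeastrine	RA	315.35	1.17	1	6	51.65	0.62	
Coptisine	CPC	320.34	3.25	0	4	30.67	0.86	
1,2-bis(4-hydroxy-3-methoxyphenyl)propan-1,3-diol	HE	320.37	1.69	4	6	52.31	0.22	
2-Hydroxy-1,5-dimethoxy-6-(methoxymethyl)-9,10-anthraquinone	RMO	328.34	2.31	1	6	95.85	0.37	
2-Hydroxy-1,8-dimethoxy-7-methoxymethylanthracenequinone	RMO	328.34	2.31	1	6	112.30	0.37	
Americanin A	RMO	328.34	2.30	3	6	46.71	0.35	
C-Homoerythrinan, 1,6-didehydro-3,15,16-trimethoxy-, (3.beta.)	HE	329.48	2.89	0	4	39.14	0.49	
1,5,7-Trihydroxy-6-methoxy-2-methoxymethylanthracenequinone	RMO	330.31	1.79	3	7	80.42	0.38	
(2R,3S)-(+)-3',5-Dihydroxy-4,7-dimethoxydihydroflavonol	RMO	332.33	1.99	3	7	77.24	0.33	
2-Hydroxyethyl 5-hydroxy-2-(2-hydroxybenzoyl)-4-(hydroxymethyl)benzoate	RMO	332.33	1.41	4	7	62.32	0.26	
Chelerythrine	CPC	332.37	4.29	0	4	34.18	0.78	menopause
Worenine	CPC	334.37	3.73	0	4	45.83	0.87	
Yinyanghuo C (2-(2,2-dimethylchromen-6-yl)-5,7-dihydroxychromen-4-one)	HE	336.36	3.39	2	5	45.67	0.50	
Berberine	CPC	336.39	3.45	0	4	36.86	0.78	menopause
Isocorypalmine	CPC	341.44	3.35	1	5	35.77	0.59	
Yinyanghuo E (5,7-dihydroxy-2-(8-hydroxy-2,2-dimethylchromen-6-yl)chromen-4-one)	HE	352.36	3.12	3	6	51.63	0.55	
Palmatine	CPC	352.44	3.65	0	4	64.6	0.65	menopause
Fumarine	CPC	353.40	2.95	0	6	59.26	0.83	menopause
Cavidine	CPC	353.45	3.72	0	5	35.64	0.81	
8-Isopentenyl-kaempferol	HE	354.38	3.63	4	6	38.04	0.39	menopause
Anhydroicaritin (3,5,7-trihydroxy-2-(4-methoxyphenyl)-8-(3-methylbut-2-enyl)chromen-4-one)	HE/RA	368.41	3.88	3	6	45.41	0.44	menopause
Suchilactone	RAS	368.41	3.73	0	6	57.52	0.56	
6-Hydroxy-11,12-dimethoxy-2,2-dimethyl-1,8-dioxo-2,3,4,8-tetrahydro-1H-isochromeno[3,4-h]isoquinolin-2-ium	HE	370.41	2.75	1	6	60.64	0.66	
Ohioensin-A	RMO	372.39	3.57	3	5	38.13	0.76	
Phellavin_qt	CPC	374.42	2.51	5	7	35.86	0.44	
Olivil	HE	376.44	1.68	4	7	62.23	0.41	
Jatrorrhizine	CPC	380.5	4.44	1	4	30.44	0.75	menopause
Stigmasterol	RC	412.77	7.64	1	1	43.83	0.76	menopause
Diosgenin ((3beta,25R)-spirost-5-en-3-ol)	RA	414.69	4.63	1	3	80.88	0.81	menopause
ZINC03982454	RC	414.79	8.08	1	1	36.91	0.76	
Beta-sitosterol	RC	414.79	8.08	1	1	36.91	0.75	menopause
Timosaponin B III_qt	RA	416.71	4.77	2	3	35.26	0.87	
Anemarsaponin C_qt	RA	416.71	4.97	2	3	35.50	0.87	
Phyllanthin	RAS	418.58	4.11	0	6	33.31	0.42	
Yinyanghuo A	HE	420.49	4.20	3	6	56.96	0.77	
Cycloartenol (9beta,19-Cyclo-24-lanosten-3beta-ol)	RC	426.80	7.55	1	1	38.69	0.78	menopause
Anemarsaponin F_qt	RA	432.71	3.92	2	4	60.06	0.79	
Asperglaucide (aurantiamide acetate)	RA	444.57	4.02	2	6	58.02	0.52	
Anemarsaponin E_qt	RA	448.76	4.53	2	4	30.67	0.86	
Obacunone	CPC	454.56	2.68	0	7	43.29	0.77	menopause
Icariside A7	HE	462.49	1.16	5	10	31.91	0.86	
Hispidone	CPC	472.78	4.46	2	4	36.18	0.83	
Kihadanin A	CPC	486.56	1.76	1	9	31.60	0.70	
Isoprincepin	RMO	494.53	2.52	5	9	49.12	0.77	
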