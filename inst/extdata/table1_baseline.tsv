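variable	unit	all_mean	all_sd	low_mean	low_sd	medium_mean	medium_sd	high_mean	high_sd	p
Age	year	59.11	15.78	63.39	14.03	60.27	15.85	53.64	15.84	<0.001
Gender	-	Female 327 (50%)	-	Female 100 (46%)	-	Female 117 (53%)	-	Female 110 (51%)	-	0.34
Height	cm	162.60	9.46	162.86	8.68	161.89	10.47	163.08	9.10	0.81
Weight	kg	61.17	11.95	59.95	12.13	60.44	11.58	63.13	11.95	<0.01
BMI	-	23.19	5.89	22.50	3.66	23.42	8.71	23.66	3.67	0.04
Albumin	g/l	37.15	4.90	31.58	3.00	37.56	1.20	42.29	2.12	<0.001
Diab	-	Diabetes 244 (37%)	-	Diabetes 121 (56%)	-	Diabetes 76 (34%)	-	Diabetes 47 (22%)	-	<0.001
SBP	mmHg	135.65	21.38	137.24	21.97	135.15	21.69	134.58	20.44	0.19
DBP	mmHg	78.97	14.20	75.74	14.55	79.37	14.42	81.79	12.98	<0.001
WBC	x10^9/l	6.88	2.28	6.88	2.46	6.77	2.40	7.00	1.94	0.58
Hb	g/l	108.11	21.78	104.12	20.54	109.05	21.70	111.15	22.55	<0.001
Urea	mmol/l	21.26	6.54	20.02	6.91	21.13	5.82	22.63	6.62	<0.001
Scr	umol/l	720.38	254.87	616.76	225.81	734.61	243.01	809.44	258.08	<0.001
K	mmol/l	4.33	0.78	4.23	0.87	4.32	0.73	4.45	0.70	<0.01
Na	mmol/l	139.17	4.87	138.51	7.06	139.13	3.66	139.88	2.71	<0.01
Cl	mmol/l	101.48	6.33	101.63	6.31	100.76	7.47	102.06	4.86	0.48
Ca	mmol/l	2.24	0.84	2.09	0.28	2.25	0.29	2.39	1.39	<0.001
P	mmol/l	1.61	0.49	1.52	0.45	1.63	0.44	1.69	0.55	<0.001
Hs-CRP	mg/l	5.66	13.29	7.45	18.04	5.73	11.19	3.78	8.69	<0.01
Glucose	mmol/l	6.19	2.94	6.74	3.88	6.09	2.13	5.74	2.45	<0.001
CO2CP	mmol/l	25.87	4.44	26.56	4.33	26.13	4.42	24.93	4.43	<0.001
GFR	ml/min	0.06	0.60	0.12	1.04	0.04	0.01	0.03	0.02	0.14
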