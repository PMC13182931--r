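variable	unit	recommended	all_mean	all_sd	low_mean	low_sd	medium_mean	medium_sd	high_mean	high_sd	p
Water	g/d	No clear numerical value. For patients with stable fluid status, the daily fluid intake should be 500 ml plus the previous day's urine output and the previous day's net peritoneal dialysis ultrafiltration amount.	1512.00	522.61	1441.07	471.74	1518.35	495.35	1574.88	585.45	<0.01
Protein	g/d	see DPI	52.52	15.78	49.91	13.48	52.50	14.43	55.09	18.50	<0.001
Fat	g/d	25% to 35% of total calories	61.28	17.76	58.63	17.49	61.71	16.84	63.45	18.61	<0.01
Carbohydrate	g/d	The recommended carbohydrate energy contribution is between 55% and 65%.	215.34	68.68	192.29	54.77	216.08	64.83	237.06	77.04	<0.001
Calories	kcal/d	see DEI	1582.30	450.26	1451.05	374.35	1593.96	423.44	1698.71	507.52	<0.001
Df	g/d	19.8 g/d	10.18	3.75	9.03	3.42	10.52	3.86	10.96	3.69	<0.001
K	mg/d	Normal 2,000 mg/d	1493.33	481.10	1388.68	428.49	1525.76	503.01	1563.75	492.45	<0.001
Na	mg/d	<2,300 mg/d	2595.51	925.01	2511.73	892.66	2628.97	879.93	2644.62	994.49	0.13
Mg	mg/d	Normal 300-330 mg/d	253.39	80.37	236.79	75.59	257.28	76.78	265.78	85.72	<0.001
Ca	mg/d	800-1,000 mg/d, <2,000 mg/d	437.14	168.42	447.75	184.32	441.10	163.93	422.98	155.83	0.12
P	mg/d	800-1,000 mg/d	799.52	244.67	764.02	220.35	804.01	227.36	829.70	277.75	<0.01
Fe	mg/d	Normal 10-18 mg/d, <42 mg/d	15.70	5.17	14.72	4.94	15.75	4.75	16.59	5.60	<0.001
Zn	mg/d	Normal 8.5-12 mg/d, <40 mg/d	8.18	2.87	7.77	2.51	8.26	2.65	8.49	3.34	<0.01
Cu	mg/d	Normal 0.7-0.8 mg/d, <8 mg/d	1.26	0.44	1.15	0.38	1.27	0.41	1.37	0.49	<0.001
Mn	mg/d	Normal 4.0-4.5 mg/d, <11 mg/d	3.92	1.56	3.51	1.27	3.96	1.38	4.28	1.87	<0.001
Se	ug/d	Normal 60 ug/d, <400 ug/d	35.71	11.36	34.44	10.95	34.96	10.25	37.68	12.50	<0.01
Retinol	ug/d	-	166.44	152.01	193.04	208.15	152.79	99.26	153.78	124.27	<0.01
Vitamin A	ug RAE/d	normal 600-770 ug RAE/d, <30 ug RAE/d	469.28	272.27	473.60	314.27	469.66	248.05	464.70	251.00	0.73
Carotene	ug/d	-	1705.64	1228.01	1503.12	1238.72	1786.06	1211.35	1824.82	1214.32	<0.01
Vitamin E	ug/d	Normal <700 ug/d	21.99	9.31	19.82	7.89	22.43	8.67	23.68	10.71	<0.001
Thiamine	mg/d	Normal 1.2-1.4 mg/d	1.24	3.73	1.90	6.25	0.85	1.16	0.96	1.07	<0.01
Riboflavin	mg/d	Normal 1.2-1.4 mg/d	1.32	3.58	2.01	6.00	0.96	1.05	1.00	0.96	<0.01
Nicotinic	mgNE/d	Normal 12-15 mg NE/d	12.45	5.15	11.59	4.41	12.43	4.51	13.32	6.19	<0.001
Ascorbic	mg/d	Male 90, female 75	88.43	48.69	80.11	51.27	91.20	45.00	93.84	48.69	<0.01
DPI	g/kg/d	1.0-1.2 g/kg/d	0.92	0.26	0.88	0.24	0.93	0.24	0.94	0.29	<0.01
DEI	kcal/kg/d	25-35 kcal/kg/d	27.60	7.37	25.44	6.70	28.29	7.13	29.04	7.76	<0.001
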