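trait	marker_id	chromosome	position_cM	nlp_E1	nlp_E2	nlp_E3	r2_E1	r2_E2	r2_E3
LY	NAU3269	A05	182.215	3.43	4.42	3.33	0.0283	0.0460	0.0305
LY	NAU5166	A10	23.423	NA	5.49	NA	NA	0.0540	NA
LY	NAU2935	A10	51.592	NA	4.00	NA	NA	0.0472	NA
LY	JESPR204	A13	59.714	4.12	3.00	NA	0.0460	0.0408	NA
LY	CIR246	D02	112.473	NA	NA	3.55	NA	NA	0.0444
LY	BNL3594	D06	7.66	NA	4.51	NA	NA	0.0765	NA
LY	TMK19	D06	70.38	4.30	2.77	3.97	0.0421	0.0321	0.0428
LY	NAU3100	D09	25.262	3.67	5.38	4.31	0.0408	0.0708	0.0541
LY	NAU2776	D10	9.452	NA	3.81	2.54	NA	0.0441	0.0276
SY	NAU3269	A05	182.215	2.25	4.16	2.43	0.0185	0.0441	0.0219
SY	CIR246	D02	112.473	NA	NA	4.23	NA	NA	0.0536
SY	BNL3594	D06	7.66	NA	4.61	NA	NA	0.0797	NA
SY	NAU3100	D09	25.262	NA	4.03	2.82	NA	0.0561	0.0384
BN	NAU6584	A03	74.975	3.53	2.29	NA	0.0393	0.0291	NA
BN	NAU3269	A05	182.215	2.08	3.52	3.45	0.0174	0.0364	0.0344
BN	BNL3594	D06	7.66	NA	3.62	NA	NA	0.0667	NA
BN	TMK19	D06	70.38	3.58	NA	2.41	0.0371	NA	0.0284
BN	NAU493	D07	113.413	3.91	NA	NA	0.0338	NA	NA
BN	NAU3100	D09	25.262	NA	3.48	NA	NA	0.0492	NA
BW	BNL1414	A09	95.911	NA	3.26	3.72	NA	0.0418	0.0445
BW	NAU4047	A12	11.118	3.29	4.17	NA	0.0332	0.0461	NA
BW	NAU3398	A13	3.311	3.47	3.46	NA	0.0565	0.0603	NA
BW	JESPR208	D09	118.225	NA	4.01	3.69	NA	0.0515	0.0445
LP	NAU3269	A05	182.215	3.54	2.21	2.72	0.0318	0.0202	0.0259
LP	NAU5166	A10	23.423	2.33	4.36	2.74	0.0180	0.0410	0.0244
LP	NAU2508	A10	128.028	4.45	3.62	4.68	0.0523	0.0481	0.0609
LP	NAU980	A11	0	3.40	NA	3.75	0.0565	NA	0.0672
LP	JESPR135	A11	55.787	3.79	6.64	3.80	0.0316	0.0645	0.0354
LP	NAU3398	A13	3.311	3.50	NA	NA	0.0499	NA	NA
LP	JESPR204	A13	59.714	3.73	2.96	2.22	0.0441	0.0396	0.0311
LP	BNL3590	D03	39.284	4.70	NA	2.89	0.0491	NA	0.0338
LP	TMK19	D06	70.38	5.97	4.58	3.67	0.0604	0.0518	0.0419
LP	NAU3100	D09	25.262	4.50	3.35	2.89	0.0535	0.0458	0.0400
LP	NAU3917	D10	31.125	NA	3.57	NA	NA	0.0403	NA
LP	BNL1404	D11	33.571	4.48	6.20	3.51	0.0381	0.0601	0.0323
LP	Gh508	D11	54.48	2.15	3.37	3.81	0.0163	0.0306	0.0354
LP	NAU2361	D11	101.215	4.05	4.30	4.03	0.0637	0.0734	0.0703
LI	NAU3269	A05	182.215	4.98	2.77	2.38	0.0492	0.0263	0.0232
LI	NAU980	A11	0	8.85	2.34	2.80	0.0896	0.0476	0.0572
LI	JESPR135	A11	55.787	NA	5.43	2.34	NA	0.0520	0.0209
LI	Gh369	A11	84.701	3.77	2.09	NA	0.0479	0.0300	NA
LI	NAU1151	A12	97.965	6.08	NA	NA	0.0563	NA	NA
LI	NAU3398	A13	3.311	6.01	2.49	NA	0.0819	0.0415	NA
LI	JESPR204	A13	59.714	NA	3.68	NA	NA	0.0481	NA
LI	CIR246	D02	112.473	4.75	3.14	NA	0.0577	0.0417	NA
LI	BNL3590	D03	39.284	3.30	2.70	3.47	0.0367	0.0313	0.0426
LI	NAU2233	D05	171.278	4.86	2.15	NA	0.0596	0.0304	NA
LI	TMK19	D06	70.38	4.83	4.02	NA	0.0519	0.0455	NA
LI	NAU3100	D09	25.262	5.90	2.74	3.47	0.0719	0.0384	0.0493
LI	NAU2776	D10	9.452	NA	NA	3.57	NA	NA	0.0430
LI	NAU3917	D10	31.125	NA	3.66	2.03	NA	0.0413	0.0245
LI	BNL1404	D11	33.571	NA	5.85	2.72	NA	0.0564	0.0250
LI	Gh508	D11	54.48	NA	3.67	3.41	NA	0.0338	0.0327
LI	NAU2361	D11	101.215	6.27	5.16	4.58	0.0940	0.0845	0.0812
SI	NAU493	D07	113.413	3.70	2.85	5.24	0.0385	0.0290	0.0575
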