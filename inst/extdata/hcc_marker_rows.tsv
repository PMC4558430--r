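stage	protein	crv	p_value	cancer_avg_exp	control_avg_exp	log2_fc
early	APP	46.52	6.09e-06	13724	14041	-0.03
early	ELAVL1	22.99	0.000329	1725	1319	0.39
early	H2AFX	14.08	0.001048	608	271	1.17
early	PRKDC	12.91	0.001176	4011	1684	1.25
early	CUL3	12.83	0.001188	1376	1606	-0.22
early	EZH2	12.22	0.001274	310	49	2.66
early	CEP250	12.05	0.001298	716	268	1.42
early	CDC20	10.89	0.001523	359	20	4.17
early	C19orf66	10.2	0.001688	1551	3166	-1.03
early	SUMO1	9.86	0.00181	2422	2982	-0.3
early	MCM4	9.76	0.001859	1308	336	1.96
early	GRB2	9.19	0.0022	3572	2608	0.45
late	ESR1	34.1	4.22e-06	245	1537	-2.65
late	ELAVL1	29.69	2.53e-05	1791	1319	0.44
late	UBD	28.54	3.38e-05	20926	1781	3.55
late	YWHAZ	27.31	4.22e-05	13323	6408	1.06
late	SIRT7	24	0.000122	456	225	1.02
late	HDAC5	22.07	0.000152	1696	840	1.01
late	HSP90AB1	14.43	0.0006	30949	14629	1.08
late	HGS	13.9	0.000659	2441	1167	1.06
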