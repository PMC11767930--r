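# Pathway	s01	s02	s03	s04	s05	s06	s07	s08
PWY-5484: glycolysis II	416.92	370.6	255.62	621.11	158.51	470.25	540.48	285.05
PWY-5484: glycolysis II|g__Bacteroides.s__Bacteroides_vulgatus	204.44	0	76.03	182.54	55.63	247.7	86.39	40.28
PWY-5484: glycolysis II|g__Bacteroides.s__Bacteroides_uniformis	47.97	80.09	0	193.16	55.81	156.84	37.37	197.56
PWY-5484: glycolysis II|g__Prevotella.s__Prevotella_copri	4.11	0	42.12	66.13	0.89	11.96	71.32	1.68
PWY-5484: glycolysis II|g__Faecalibacterium.s__Faecalibacterium_prausnitzii	56.07	0	12.04	144.89	32.63	41.37	13.57	20.18
PWY-5484: glycolysis II|g__Escherichia.s__Escherichia_coli	104.33	17.87	0	34.39	13.54	12.38	331.83	25.34
FASYN-ELONG-PWY: fatty acid elongation	238.47	577.74	388.05	114.82	382.35	410.27	508.78	105.28
FASYN-ELONG-PWY: fatty acid elongation|g__Bacteroides.s__Bacteroides_vulgatus	210.8	139.81	175.95	0	22.16	184.87	298.27	18.65
FASYN-ELONG-PWY: fatty acid elongation|g__Bacteroides.s__Bacteroides_uniformis	0	288.9	59.17	100.53	46.91	8.32	134.04	28.2
FASYN-ELONG-PWY: fatty acid elongation|g__Prevotella.s__Prevotella_copri	2.1	66.57	67.02	0	45.92	59.69	4.92	41.8
FASYN-ELONG-PWY: fatty acid elongation|g__Faecalibacterium.s__Faecalibacterium_prausnitzii	17.01	58.32	64.48	8.21	214.66	115.28	59.13	0
FASYN-ELONG-PWY: fatty acid elongation|g__Escherichia.s__Escherichia_coli	1.55	24.15	21.43	0.6	52.71	0	12.43	1.28
PWY-6305: putrescine biosynthesis IV	481.41	325.29	109.64	376.05	78.46	134.28	121.81	289.57
PWY-6305: putrescine biosynthesis IV|g__Bacteroides.s__Bacteroides_vulgatus	4.57	88.12	14.77	0	4.6	6.81	18.45	109.49
PWY-6305: putrescine biosynthesis IV|g__Bacteroides.s__Bacteroides_uniformis	75.23	62.89	3.98	0	18.63	63.83	11.19	35.92
PWY-6305: putrescine biosynthesis IV|g__Prevotella.s__Prevotella_copri	33.29	128.12	16.97	46.38	22.81	36.57	19.49	0
PWY-6305: putrescine biosynthesis IV|g__Faecalibacterium.s__Faecalibacterium_prausnitzii	0	29.22	57.31	49.44	9.9	13.56	44.41	94.56
PWY-6305: putrescine biosynthesis IV|g__Escherichia.s__Escherichia_coli	33.78	16.95	0	31.38	22.53	13.5	28.28	40.58
BIOTIN-PWY: biotin biosynthesis	361.63	443.36	416.05	51.89	305.79	410.87	458.89	167.99
BIOTIN-PWY: biotin biosynthesis|g__Bacteroides.s__Bacteroides_vulgatus	83.09	0	46.47	10.71	33.1	174.98	26.52	62.27
BIOTIN-PWY: biotin biosynthesis|g__Bacteroides.s__Bacteroides_uniformis	51.53	21.17	0	1.01	29.01	144.07	63.88	44.05
BIOTIN-PWY: biotin biosynthesis|g__Prevotella.s__Prevotella_copri	118.42	168.47	183.58	23.54	24.45	24.75	0	13.47
BIOTIN-PWY: biotin biosynthesis|g__Faecalibacterium.s__Faecalibacterium_prausnitzii	8.58	0	5.26	13.8	206.54	3.36	185.6	46.31
BIOTIN-PWY: biotin biosynthesis|g__Escherichia.s__Escherichia_coli	100.01	37.32	69.21	2.83	12.68	0	174.27	1.89
UNMAPPED	39.61	31.09	37.93	30.74	18.26	11.04	36.88	14.54
UNINTEGRATED|g__Escherichia.s__Escherichia_coli	4.78	6.46	2.38	3.92	6.15	5.24	7.16	1.97
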