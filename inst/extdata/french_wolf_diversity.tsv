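locus	name	na	ho	he	fis
L01	AHT103	7	0.137	0.138	0.019
L02	AHT111	8	0.572	0.578	0.008
L03	AHTk211	8	0.128	0.505	0.758
L04	FH2096	6	0.557	0.554	-0.013
L05	CPH02	8	0.553	0.583	0.041
L06	FH2088	7	0.596	0.602	0.017
L07	C09.173	5	0.606	0.626	0.032
L08	CPH05	6	0.646	0.633	-0.02
L09	FH2004	15	0.63	0.724	0.105
L10	CFX30371	4	0.068	0.13	0.508
L11	CXX279	8	0.455	0.646	0.306
L12	C09.250	7	0.734	0.714	-0.031
L13	FH2161	15	0.673	0.754	0.08
L14	FH2140	13	0.613	0.619	0.004
L15	INU030	6	0.148	0.151	0.016
L16	FH2137	16	0.779	0.795	0.011
L17	FH2054	9	0.789	0.77	-0.024
L18	C27.442	6	0.299	0.306	0.025
L19	Dbar1	11	0.051	0.053	0.024
L20	REN162C04	9	0.413	0.4	-0.032
L21	PEZ17	8	0.642	0.653	0.006
L22	FH2010	6	0.446	0.48	0.057
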