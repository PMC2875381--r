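mcr	cytoband	start	end	width	peak	n_tumors	n_genes	candidates	known_cnv
1	1q21.1	142480203	144454599	1974396	1.14	2	40	PDE4DIP,BCL9	yes
2	1q24.1	162608779	163764545	1155766	1.51	2	13	GPA33	partial
3	2q31.1	175489973	176859506	1369533	1.16	6	15	HOXD11,HOXD13,CHN1	no
4	5p13.3	31589913	32485015	895102	1.15	2	6		yes
5	11q24.2	125577665	125652604	74939	1.14	4	4		no
6	20q13.33	59983746	60209329	225583	1.03	3	6	SS18L1	partial
7	1p21.2	101168629	101448588	279959	-1.06	2	3		no
8	6q27	169921072	170019433	98361	-1.31	3	5		no
9	9p24.1	5899734	6247371	347637	-1.17	2	5		no
10	11q21	93552953	93872148	319195	-1.10	2	6	MRE11A	no
11	11q23.3	120465281	120683610	218329	-1.43	4	3		no
12	14q21.1	37749185	38688955	939770	-1.46	6	8		partial
13	15q26.3	98987639	99630115	642476	-1.24	4	9		yes
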