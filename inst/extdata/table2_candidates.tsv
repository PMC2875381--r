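chrom	start	end	width	probe_id	rel_exp	q	symbol	gene_id	description	known_cnv
1	189881478	193480076	3598598	219918_s_at	2.63	0.00	ASPM	259266	asp-like, microcephaly associated (Drosophila)	yes
6	29678435	30145591	467156	216229_x_at	2.02	0.00	HCG2P7	80867	HLA complex group 2 pseudogene 7	yes
6	31649132	31733853	84721	212384_at	2.08	0.00	BAT1	7919	HLA-B associated transcript 1	yes
7	6503371	10915738	4412367	209507_at	2.37	0.00	RPA3	6119	replication protein A3, 14kDa	no
7	16413351	17606374	1193023	217979_at	2.75	0.00	TM4SF13	27075	transmembrane 4 superfamily member 13	no
7	21258989	24511806	3252817	203820_s_at	2.60	0.00	IMP-3	10643	IGF-II mRNA-binding protein 3	no
7	26009673	26923158	913485	204362_at	2.35	0.00	SCAP2	8935	src family associated phosphoprotein 2	no
7	26009673	26923158	913485	201091_s_at	2.21	0.00	CBX3	11335	chromobox homolog 3	no
7	31602638	38147471	6544833	204051_s_at	3.03	0.00	SFRP4	6424	secreted frizzled-related protein 4	no
7	31602638	38147471	6544833	212792_at	2.31	0.00	KIAA0877	23333	KIAA0877 protein	no
7	31602638	38147471	6544833	202904_s_at	2.07	0.00	LSM5	23658	LSM5 homolog, U6 small nuclear RNA associated	no
7	55852994	55943507	90513	205194_at	2.36	0.00	PSPH	5723	phosphoserine phosphatase	no
7	64310010	72299706	7989696	213460_x_at	2.18	0.00	WBSCR20C	55695	Williams Beuren syndrome chromosome region 20C	yes
7	73393701	76470379	3076678	213670_x_at	2.25	0.00	WBSCR20B	155400	Williams-Beuren Syndrome critical region protein 20, copy B	yes
7	89659035	96294973	6635938	204873_at	2.03	0.00	PEX1	5189	peroxisome biogenesis factor 1	no
7	89659035	96294973	6635938	209278_s_at	5.37	0.00	TFPI2	7980	tissue factor pathway inhibitor 2	no
7	89659035	96294973	6635938	204688_at	2.01	0.00	SGCE	8910	sarcoglycan, epsilon	yes
7	89659035	96294973	6635938	215483_at	2.26	0.00	AKAP9	10142	A kinase (PRKA) anchor protein (yotiao) 9	yes
7	89659035	96294973	6635938	212094_at	2.44	0.00	PEG10	23089	paternally expressed 10	no
7	96294973	97126111	831138	205047_s_at	2.51	0.00	ASNS	440	asparagine synthetase	yes
7	97586138	99133331	1547193	213479_at	3.27	0.00	NPTX2	4885	neuronal pentraxin II	no
7	99463598	99609889	146291	220954_s_at	2.37	0.00	PILRB	29990	paired immunoglobin-like type 2 receptor beta	no
7	100130869	101618306	1487437	205586_x_at	2.03	0.01	VGF	7425	VGF nerve growth factor inducible	no
7	105325416	106944473	1619057	206529_x_at	2.25	0.00	SLC26A4	5172	solute carrier family 26, member 4	no
7	106993757	107808465	814708	202843_at	2.19	0.00	DNAJB9	4189	DnaJ (Hsp40) homolog, subfamily B, member 9	no
7	109897338	112000722	2103384	202147_s_at	2.05	0.00	IFRD1	3475	interferon-related developmental regulator 1	no
7	115794692	116151838	357146	203510_at	3.15	0.00	MET	4233	met proto-oncogene	no
7	127965509	128048784	83275	214845_s_at	2.04	0.00	CALU	813	calumenin	no
17	61638666	62311370	672704	213093_at	2.12	0.00	PRKCA	5578	protein kinase C, alpha	no
17	73732314	75521030	1788716	202095_s_at	2.20	0.00	BIRC5	332	baculoviral IAP repeat-containing 5 (survivin)	no
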