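gene	rs_id	allele1	allele2	case_allele1	case_allele2	control_allele1	control_allele2
CDKN1A	rs1801270	C	A	74	22	157	57
TP53	rs1042522	G	C	52	44	112	102
TP53	rs1800371	C	T	96	0	213	1
ATM	rs1801516	G	A	82	14	202	12
ATM	rs1801673	A	T	96	0	214	0
HDM2	rs7484572	G	C	96	0	214	0
HDM2	rs2279744	T	G	71	25	125	89
HDM2	rs1196333	T	A	95	1	198	16
TGFB1	rs9282871	G	A	95	1	213	1
TGFB1	rs1982073	C	T	40	56	102	112
TGFB1	rs1800471	G	C	92	4	207	7
TGFB1	rs4987025	C	T	96	0	214	0
TGFB1	rs1800469	C	T	67	29	122	92
TGFB1	rs11466314	G	A	96	0	213	1
TGFB1	rs35318502	C	T	96	0	214	0
TGFB1	rs8179182	wt	del	94	2	214	0
TGFB1	rs35383147	C	A	96	0	214	0
TGFB1	rs34233206	wt	ins	96	0	214	0
TGFB1	rs1800472	C	T	92	4	199	15
TGFB1	rs11466334	C	T	95	1	213	1
XRCC1	rs2271980	G	A	96	0	214	0
XRCC1	rs25487	G	A	83	13	155	59
XRCC1	rs3213368	C	T	87	9	193	21
XRCC1	rs2139720	G	A	88	8	190	24
XRCC1	rs3213369	C	T	96	0	213	1
XRCC3	rs41285494	G	A	96	0	214	0
XRCC3	rs861539	G	A	55	41	133	81
XRCC3	rs3212112	A	C	95	1	213	1
XRCC3	rs3212113	C	T	96	0	214	0
XRCC4	rs2974446	A	C	96	0	214	0
XRCC4	rs3734091	G	T	95	1	213	1
XRCC5	rs41296835	A	G	96	0	213	1
XRCC5	rs1051677	T	C	89	7	178	36
XRCC5	rs41437350	G	T	96	0	214	0
XRCC5	rs1051685	A	G	85	11	195	19
PRKDC	rs7830743	T	C	93	3	197	17
PRKDC	rs8178228	A	G	96	0	214	0
LIG4	rs1805384	T	C	90	6	200	14
LIG4	rs1805383	C	A	96	0	214	0
LIG4	rs4987182	C	T	93	3	209	5
LIG4	rs1805389	C	T	95	1	206	8
LIG4	rs1805388	C	T	91	5	195	19
LIG4	rs2232636	G	A	96	0	214	0
LIG4	rs2232641	G	A	96	0	214	0
LIG4	rs3093766	A	G	96	0	214	0
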