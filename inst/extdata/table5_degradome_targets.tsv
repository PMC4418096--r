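sno	mirna	target	rnahybrid_predicted	cat_pbs	cat_scr	cat_antimir	go_term	cleavage_position	cleavage_position_primary	ortholog	curation
1	miR-989	ASTE002227	TRUE	2	4	2	protein binding	500	500	AGAP003558	printed
2	miR-989	ASTE014169	FALSE	0	0	0		151	151		printed
3	miR-989	ASTE004090	FALSE	3	3	4	signal transduction	3429	3429	AGAP002261	printed
4	miR-989	ASTE010155	FALSE	0			DNA binding	840	840	AGAP003982	printed
5	miR-989	ASTE008099	FALSE	4			protein binding	553	553	AGAP003439	printed
6	miR-989	ASTE003651	FALSE	4			aminoacyl-tRNA ligase activity	1680	1680	AGAP004708	printed
7	miR-989	ASTE007120	FALSE	4	2	2		2092 and 1931	2092	AGAP000879	printed
8	miR-989	ASTE014120	FALSE	2	4	2		275	275		printed
9	miR-989	ASTE010290	FALSE	4	2	2		1682	1682	AGAP005504	printed
10	miR-989	ASTE002911	FALSE	2	4	2	nucleic acid binding	731	731	AGAP004361	printed
11	miR-989	ASTE008381	TRUE	4		2		984	984	AGAP010075	antimir_inferred
12	miR-989	ASTE004431	FALSE	4			proteolysis	1824	1824	AGAP007280	printed
13	miR-989	ASTE003701	TRUE	4				795	795	AGAP010226	printed
14	miR-989	ASTE011654	FALSE	2	3	2		2304	2304		printed
15	miR-989	ASTE005749	TRUE	4				2347	2347	AGAP001150	printed
16	miR-989	ASTE003996	FALSE	2		4	integral component of membrane	1681	1681	AGAP004486	antimir_inferred
17	miR-219	ASTE006120	FALSE	4				1650	1650	AGAP004892	printed
18	miR-219	ASTE006196	FALSE	4			proteolysis	4239	4239	AGAP006203	printed
19	miR-219	ASTE011346	FALSE	4				1764	1764	AGAP004892	printed
20	miR-219	ASTE007196	FALSE	4				1442	1442	AGAP001357	printed
21	miR-219	ASTE002692	FALSE	4			GTP binding	1763	1763	AGAP009441	printed
22	miR-219	ASTE009304	FALSE	4			protein binding	1268	1268	AGAP011439	printed
23	miR-285	ASTE005579	FALSE	2			acid phosphatase activity	337	337	AGAP002387	printed
24	miR-7	ASTE008161	FALSE	4				428	428	AGAP010789	printed
25	miR-7	ASTE001260	FALSE	4				677	677	AGAP008905	printed
26	miR-7	ASTE008160	FALSE	4				383	383	AGAP010789	printed
27	miR-7	ASTE010939	FALSE	4				2608	2608	AGAP012493	printed
28	miR-7	ASTE002046	FALSE	4			ATP binding	211	211	AGAP002996	printed
29	miR-7	ASTE003640	FALSE	2			metabolic process	1342	1342	AGAP004721	printed
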