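chrom	all_indels	all_snps	all_total	bi_indels	bi_snps	bi_total
1	147722	1357453	1505175	126369	1349565	1475934
2	97645	899301	996946	83781	893743	977524
3	93450	868813	962263	80354	863936	944290
4	91653	852027	943680	78769	846792	925561
5	76667	690517	767184	65553	686424	751977
6	74571	674296	748867	63869	670070	733939
7	79382	727068	806450	68070	722632	790702
8	80305	776161	856466	69441	771166	840607
9	64599	603074	667673	55591	599656	655247
10	72890	649547	722437	62265	645511	707776
11	48745	419897	468642	41227	417041	458268
12	41910	427686	469596	37294	423529	460823
13	38426	363283	401709	32834	360942	393776
14	73042	668303	741345	62609	664494	727103
15	72635	679471	752106	62273	675408	737681
16	68916	635961	704877	58733	632351	691084
17	69046	642029	711075	59593	638266	697859
18	71768	664346	736114	61759	660204	721963
19	54275	508176	562451	46645	505024	551669
20	74882	693542	768424	66477	683845	750322
21	50108	484203	534311	43275	481038	524313
22	39885	385028	424913	34402	382654	417056
23	43983	398492	442475	37631	396114	433745
24	40132	376887	417019	34381	374407	408788
25	30733	291433	322166	26275	289800	316075
26	38294	381680	419974	33366	379107	412473
27	36748	348404	385152	31760	346037	377797
28	36445	347184	383629	31480	345095	376575
29	32311	313570	345881	28037	311406	339443
30	28951	269626	298577	25025	267744	292769
31	22581	212724	235305	19245	211489	230734
X	97952	754114	852066	84521	749848	834369
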