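sample	contig	junction5	junction3	gene	tsm_type	tsm_size	donor_start	donor_end	strand	twin_priming	insertion_bp	lower_bound	internal_dup	read_count	validated	wgs_detected	wgs_read_count
c985T	1	195769724	195769709	intergenic	duplication	16	29065826	29066121	+	present	295	FALSE	FALSE	3984	yes	yes	15
c985T	4	93280482	93280454	GRID2	duplication	28	29065650	29065893	+	absent	243	FALSE	FALSE	4658	no	yes	20
c985T	4	155900401	155900387	intergenic	duplication	14	29064889	29065912	+	present	1015	FALSE	FALSE	1705	no	yes	9
c985T	4	183051382	183051401	AC108142.1	deletion	18	29065306	29065448	-	absent	142	FALSE	FALSE	10103	no	yes	8
c985T	7	146783241	146783223	CNTNAP2	duplication	18	29065369	29065912	-	present	536	FALSE	FALSE	19889	no	yes	29
c985T	7	152661949	152661940	intergenic	duplication	9	29065283	29065887	-	present	455	FALSE	FALSE	20107	no	yes	19
c985T	12	33708291	33708277	intergenic	duplication	14	29065722	29066121	-	present	377	FALSE	FALSE	16909	no	yes	20
c985T	2	78612537	78612530	intergenic	duplication	8	29065453	29066118	-	present	665	FALSE	FALSE	5	no	no	0
c985T	3	99147126	99147111	intergenic	duplication	16	29065138	29066126	-	present	984	FALSE	FALSE	47	no	no	0
c985T	4	90987152	90987149	intergenic	duplication	4	29065287	29066121	+	absent	834	FALSE	FALSE	99	no	no	0
c985T	6	74978206	74978187	RP11-554D15.1	duplication	20	29065521	29066118	+	absent	597	FALSE	FALSE	9	no	no	0
c985T	8	111856478	111856457	intergenic	duplication	22	29064270	29066083	-	present	857	FALSE	FALSE	6	no	no	0
c985T	14	99070525	99070523	intergenic	duplication	3	29065558	29065912	-	absent	354	FALSE	FALSE	55	yes	no	1
c985T	16	26220799	26220798	intergenic	duplication	2	29065976	29066118	+	absent	142	FALSE	FALSE	182	no	no	0
c985T	16	5902138	5902158	RP11-420N3.2	deletion	19	29065747	29065912	-	absent	165	FALSE	FALSE	72	no	no	1
c368T	1	115147190	115147187	DENND2C	duplication	4	29065647	29065893	-	absent	246	FALSE	FALSE	12753	no	yes	18
c368T	2	182004540	182004515	AC104820.2	duplication	26	29065285	29065886	+	present	783	FALSE	TRUE	20217	no	yes	12
c368T	2	229159082	229159075	intergenic	duplication	8	29065578	29065908	-	absent	330	FALSE	FALSE	704	no	yes	16
c368T	6	70787202	70787188	COL19A1	duplication	15	29065808	29066032	NA	present	223	TRUE	FALSE	17007	no	yes	21
c368T	6	133527459	133527443	intergenic	duplication	17	29065683	29065887	-	absent	204	FALSE	FALSE	98	no	yes	9
c368T	8	88681299	88681304	AF121898.3	deletion	4	29065471	29065887	+	absent	416	FALSE	FALSE	1095	no	yes	6
c368T	12	128116403	128116405	RP11-526P6.1	deletion	1	29065730	29066121	-	absent	391	FALSE	FALSE	15099	no	yes	10
c368T	2	50947578	50947612	NRXN1	deletion	33	29065849	29066032	NA	NA	183	TRUE	FALSE	98	no	no	0
c368T	2	129889238	129889240	intergenic	deletion	1	29065945	29066121	-	absent	176	FALSE	FALSE	193	no	no	0
c368T	4	44621421	44621515	intergenic	deletion	93	29065305	29065912	-	absent	607	FALSE	FALSE	33	no	no	0
c368T	5	8665955	8665942	intergenic	duplication	14	29065849	29066091	+	absent	242	FALSE	FALSE	451	yes	no	0
c368T	5	83347372	83347360	EDIL3	duplication	13	29065762	29066121	+	present	340	FALSE	FALSE	78	no	no	0
c368T	5	119565858	119565843	intergenic	duplication	16	29065419	29065899	+	present	455	FALSE	FALSE	14	no	no	0
c368T	6	112763097	112763084	intergenic	duplication	14	29065288	29066118	+	present	671	FALSE	FALSE	38	no	no	0
c368T	7	152870668	152870685	intergenic	deletion	16	29065491	29065912	-	present	306	FALSE	FALSE	457	yes	no	0
c368T	8	114925191	114925178	intergenic	duplication	14	29064763	29065887	-	absent	1124	FALSE	FALSE	1020	yes	no	0
c368T	8	107979180	107979169	intergenic	duplication	12	29064270	29066121	-	present	1055	FALSE	FALSE	28	no	no	0
c368T	10	101386670	101386662	intergenic	duplication	9	29065621	29065782	NA	NA	161	TRUE	FALSE	36	no	no	0
c368T	10	107557372	107557435	intergenic	NA	NA	29065912	29066032	NA	NA	120	TRUE	FALSE	86	no	no	1
c368T	12	33100097	33100084	intergenic	duplication	14	29065445	29066118	-	present	670	FALSE	FALSE	248	yes	no	0
c368T	14	79638932	79638931	NRXN3	duplication	2	29065974	29066121	-	absent	147	FALSE	FALSE	172	yes	no	1
c368T	18	1233989	1233975	intergenic	duplication	15	29065387	29066121	-	present	735	FALSE	FALSE	117	no	no	0
c368T	X	108351909	108351907	intergenic	duplication	3	29065437	29065893	-	absent	456	FALSE	FALSE	119	no	no	0
c368T	Y	15633117	15633103	intergenic	duplication	15	29065877	29066121	-	absent	244	FALSE	FALSE	1084	yes	no	1
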