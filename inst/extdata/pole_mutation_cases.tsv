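case	protein_change	mutation_type	exonuclease_domain	nonsyn_snv_count	classification
1	P286R	Missense	Yes	9515	pole_category
2	P286R	Missense	Yes	7351	pole_category
3	P286R	Missense	Yes	3963	pole_category
4	Y1813C	Missense	No	3385	common_hypermutator
5	P286R	Missense	Yes	3344	pole_category
6	P286R	Missense	Yes	2847	pole_category
7	F367C	Missense	Yes	2632	pole_category
8	P286R	Missense	Yes	2606	pole_category
9	P286R	Missense	Yes	1870	pole_category
10	V411L	Missense	Yes	1859	pole_category
11	P1207S, V1218I	Missense	No	1782	common_hypermutator
12	S297Y	Missense	Yes	1698	pole_category
13	E767D	Missense	No	1495	common_hypermutator
14	E1199D	Missense	No	1289	common_hypermutator
15	K879E, R1626H	Missense	No	1274	common_hypermutator
16	K391T	Missense	Yes	1120	common_hypermutator
17	T2049A	Missense	No	1110	common_hypermutator
18	Q196*	Nonsense	Yes	1041	common_hypermutator
19	R47W	Missense	No	723	common_hypermutator
20	R1289C	Missense	No	188	nonhypermutator
21	T1904A	Missense	No	157	nonhypermutator
22	V533M	Missense	No	119	nonhypermutator
23	D1131E	Missense	No	97	nonhypermutator
24	K1942*	Nonsense	No	60	nonhypermutator
25	Q125H	Missense	Yes	51	nonhypermutator
26	A1200T	Missense	No	45	nonhypermutator
27	R259H	Missense	Yes	36	nonhypermutator
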