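# Worked example, right-hand block: top 50 up-regulated probe sets for
# the prostate model class after removal of the mouse cross-hybridizing
# component. Entries ranked below 50 pre-mask refill the list from
# below (e.g. LAMB3's slot is taken over by entries such as 217875_s_at
# PMEPA1). Transcribed from the published run-on table.
rank	probe_set_id	gene_symbol	fold_change
1	202859_x_at	IL8	5.290
2	206336_at	CXCL6	5.190
3	209183_s_at	C10orf10	4.672
4	223333_s_at	ANGPTL4	4.479
5	211506_s_at	IL8	4.451
6	201438_at	COL6A3	4.328
7	212977_at	CXCR7	4.231
8	1570537_a_at		4.170
9	211756_at	PTHLH	4.153
10	203828_s_at	IL32	3.987
11	241436_at	SCNN1G	3.967
12	214157_at	GNAS	3.756
13	221009_s_at	ANGPTL4	3.744
14	213711_at	KRT81	3.485
15	206300_s_at	PTHLH	3.460
16	1569978_x_at		3.456
17	211071_s_at	MLLT11	3.355
18	201578_at	PODXL	3.249
19	222449_at	PMEPA1	3.230
20	205199_at	CA9	3.189
21	201890_at	RRM2	3.106
22	211030_s_at	SLC6A6	3.100
23	222608_s_at	ANLN	3.062
24	210095_s_at	IGFBP3	3.028
25	207291_at	PRRG4	3.006
26	209774_x_at	CXCL2	2.979
27	211161_s_at	COL3A1	2.974
28	206157_at	PTX3	2.970
29	203373_at	SOCS2	2.969
30	232381_s_at	DNAH5	2.929
31	212143_s_at	IGFBP3	2.928
32	238513_at	PRRG4	2.922
33	201291_s_at	TOP2A	2.911
34	202404_s_at	COL1A2	2.908
35	205479_s_at	PLAU	2.892
36	205680_at	MMP10	2.803
37	217875_s_at	PMEPA1	2.797
38	230280_at	TRIM9	2.763
39	227556_at	NME7	2.723
40	242517_at	KISS1R	2.699
41	218691_s_at	PDLIM4	2.688
42	219148_at	PBK	2.684
43	203691_at	PI3	2.684
44	202998_s_at	LOXL2	2.681
45	210538_s_at	BIRC3	2.669
46	229435_at	GLIS3	2.667
47	41469_at	PI3	2.649
48	218355_at	KIF4A	2.624
49	214438_at	HLX	2.623
50	209156_s_at	COL6A2	2.597
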