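# Worked example: top 50 up-regulated probe sets for the prostate model
# class (PC-3 and PC-3/M), in vitro (P0) -> first in vivo passage (P1)
# average fold change, before removal of mouse cross-hybridizing probe
# sets. n_mouse_samples is the number of mouse RNA samples (out of 5) in
# which the probe set was detected; 0 = not cross-hybridizing.
# Transcribed from the published run-on table. Two flag assignments are
# ambiguous at the 0.001 fold-change level in the printed text; they are
# resolved here as 2.830 + flag 1 (227140_at INHBA) and 2.829 + flag 1
# (211668_s_at PLAU), which reproduces the printed total of 14 flagged
# probe sets.
rank	probe_set_id	gene_symbol	fold_change	n_mouse_samples
1	231628_s_at	SERPINB6	8.169	5
2	216405_at		6.239	5
3	217683_at	HBE1	6.171	5
4	202859_x_at	IL8	5.290	0
5	206336_at	CXCL6	5.190	0
6	209183_s_at	C10orf10	4.672	0
7	204470_at	CXCL1	4.551	1
8	223333_s_at	ANGPTL4	4.479	0
9	211506_s_at	IL8	4.451	0
10	201438_at	COL6A3	4.328	0
11	217572_at		4.301	5
12	212977_at	CXCR7	4.231	0
13	1570537_a_at		4.170	0
14	211756_at	PTHLH	4.153	0
15	203828_s_at	IL32	3.987	0
16	241436_at	SCNN1G	3.967	0
17	215076_s_at	COL3A1	3.775	5
18	202912_at	ADM	3.763	1
19	214157_at	GNAS	3.756	0
20	221009_s_at	ANGPTL4	3.744	0
21	224344_at	COX6A1	3.700	5
22	213711_at	KRT81	3.485	0
23	201852_x_at	COL3A1	3.483	5
24	206300_s_at	PTHLH	3.460	0
25	1569978_x_at		3.456	0
26	211071_s_at	MLLT11	3.355	0
27	201578_at	PODXL	3.249	0
28	222449_at	PMEPA1	3.230	0
29	205199_at	CA9	3.189	0
30	201890_at	RRM2	3.106	0
31	211030_s_at	SLC6A6	3.100	0
32	1570107_at		3.091	5
33	222608_s_at	ANLN	3.062	0
34	210095_s_at	IGFBP3	3.028	0
35	207291_at	PRRG4	3.006	0
36	209270_at	LAMB3	3.002	2
37	209774_x_at	CXCL2	2.979	0
38	211161_s_at	COL3A1	2.974	0
39	206157_at	PTX3	2.970	0
40	203373_at	SOCS2	2.969	0
41	232381_s_at	DNAH5	2.929	0
42	212143_s_at	IGFBP3	2.928	0
43	238513_at	PRRG4	2.922	0
44	201291_s_at	TOP2A	2.911	0
45	202404_s_at	COL1A2	2.908	0
46	223484_at	C15orf48	2.896	1
47	205479_s_at	PLAU	2.892	0
48	227140_at	INHBA	2.830	1
49	211668_s_at	PLAU	2.829	1
50	205680_at	MMP10	2.803	0
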