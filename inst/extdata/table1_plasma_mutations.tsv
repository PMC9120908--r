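subject	gene	hgvs_c	protein	tissue_vaf	plasma_vaf	aneuploidy_score
2	TP53	c.659A>G	Y220C	52.38	Failed	1.49
3	ERBB2	c.2264T>C	L755S	53.41	19.53	7.7
7	TP53	c.743G>A	R248Q	39.24	Failed	1.06
7	ERBB2	c.929C>T	S310F	27.69	Failed	1.06
10	TP53	c.517G>A	V173M	46.67	Failed	1.22
11	CTNNB1	c.134C>T	S45F	36.36	0	1.99
18	PIK3CA	c.1633G>A	E545K	20.79	Failed	1.24
23	TP53	c.742C>T	R248W	86.84	24.28	25.35
29	FBXW7	c.1514G>A	R505H	30.39	19.61	7.54
32	TP53	c.853G>A	E285K	47.87	41.3	69.89
33	PIK3CA	c.3140A>G	H1047R	30.07	0.87	2.43
33	TP53	c.659A>G	Y220C	30.56	0.9	2.43
41	PIK3CA	c.1633G>A	E545K	31.36	4.83	1.72
41	CTNNB1	c.134C>T	S45F	30.77	3.7	1.72
43	TP53	c.574C>T	Q192Ter	26.60	10.24	9.22
45	FBXW7	c.1513C>G	R505G	38.52	0	0.65
45	PIK3CA	c.1633G>A	E545K	16.54	0	0.65
47	FBXW7	c.1513C>G	R505G	48.98	0	2.23
48	TP53	c.742C>T	R248W	61.33	2.94	1.75
53	CTNNB1	c.110C>G	S37C	38.10	2.69	0.74
53	TP53	c.589G>A	V197M	55.52	3.693	0.74
55	TP53	c.532dup	H178PfsTer3	53.85	0	5.81
60	PIK3CA	c.1624G>C	E542Q	27.73	4.88	5.11
60	PIK3CA	c.1633G>A	E545K	26.92	4.878	5.11
68	TP53	c.517G>A	V173M	47.58	0.6	2.24
70	TP53	c.586C>T	R196Ter	12.64	5.17	8.54
78	PIK3CA	c.1624G>A	E542K	10.99	3.21	2.59
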