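probe_id	p	q	affected_range_pct	healthy_range_pct	range_diff_pp	mean_meth_pct	chromosome	position	gene_name	gene_region
cg00002719	9e-07	0.039	34.8	1.7	33.2	3.9	1	169396706	CCDC181	TSS200
cg00100121	3e-06	0.049	42.1	2.2	39.9	3.6	1	169396635	CCDC181	1stExon;5'UTR
cg08104202	4e-06	0.049	35.1	2	33	8.4	1	169396712	CCDC181	TSS200
cg05100739	4e-06	0.049	15.3	1	14.4	5.7	17	72733163	RAB37	TSS200;1stExon;Body;TSS200
cg08530065	2e-06	0.042	22.5	1.3	21.3	86.6	13	39980228	LHFP	Body
cg10717290	3e-07	0.034	25.6	1	24.6	9.2	7	119913576	KCND2	TSS200
cg11796442	2e-06	0.049	35.2	1.8	33.4	17.8	5	72593919	-	-
cg12469257	3e-06	0.049	19.2	1.2	18	88.5	3	25761040	NGLY1	3'UTR;Body;Body;Body
cg15240852	3e-06	0.049	17.2	1	16.2	90.9	3	131083585	NUDT16P	Body
cg22058112	1e-06	0.041	15.9	1	15.2	7.4	15	42566300	TMEM87A;GANC	TSS1500;TSS200
cg22070855	8e-07	0.039	32.9	1.6	31.3	17.4	3	172167527	GHSR	TSS1500
cg24599017	1e-07	0.03	14.6	0.4	14.2	96.3	5	178835885	-	-
cg24932449	4e-06	0.049	26.2	1.6	24.7	91.5	11	2672613	KCNQ1;KCNQ1OT1	Body;Body
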