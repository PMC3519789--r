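chromosome	n_genes	length_cM	D	Dstar_published	p_published
1	166	180.6	0.0990	1.2812	<=0.01
2	177	185.3	0.0444	0.5948	>0.15
3	145	172.6	0.1483	1.7946	<=0.01
4	134	168.3	0.1286	1.4967	<=0.01
5	149	167.1	0.0490	0.6013	>0.15
6	141	180.3	0.1373	1.6451	<=0.01
7	160	204.5	0.0961	1.2207	<=0.01
8	173	157.4	0.0774	1.0226	<=0.02
9	142	145.8	0.0914	1.0953	<=0.01
10	136	120.4	0.1208	1.4219	<=0.01
11	143	171.2	0.0933	1.1219	<=0.01
12	135	131.7	0.1032	1.2051	<=0.01
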