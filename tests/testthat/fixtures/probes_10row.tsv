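probe_id	gene_id	tissue	dpa	array_id	cy5	cy3	flag	strand
Nvg00001_r01	Nvg00001	FL	1	A_FL_1	1234.5	1000	ok	plain
Nvg00001_r02	Nvg00001	FL	1	A_FL_1	1190	980	ok	plain
Nvg00002_r01	Nvg00002	FL	1	A_FL_1	50	4000	bad	plain
Nvg00002i_r01	Nvg00002	FL	1	A_FL_1	800	820	ok	inverted
CTRL0001	CTRL0001	FL	1	A_FL_1	1500	1490	control	plain
Nvg00001_r01	Nvg00001	SC	3	A_SC_3	2400	1210	ok	plain
Nvg00001_r02	Nvg00001	SC	3	A_SC_3	2380	1180	ok	plain
Nvg00002_r01	Nvg00002	SC	3	A_SC_3	600	590	ok	plain
Nvg00002i_r01	Nvg00002	SC	3	A_SC_3	610	630	ok	inverted
CTRL0001	CTRL0001	SC	3	A_SC_3	1480	1500	control	plain
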