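gene_id	symbol	catagen_fpkm	anagen_fpkm	log2fc_printed	pvalue	qvalue
108636076	LOC108636076	3.27552	2.18113	0.586645	5.00E-05	0.00453085
102190274	LOC102190274	69.5476	108.324	-0.639287	5.00E-05	0.00453085
108635596	LOC108635596	496.322	332.291	0.578828	5.00E-05	0.00453085
XLOC_016760	XLOC_016760	0.679671	0.270519	1.32911	5.00E-05	0.00453085
108635657	LOC108635657	176.509	119.452	0.563313	5.00E-05	0.00453085
108636746	LOC108636746	349.081	2088.57	-2.58088	5.00E-05	0.00453085
XLOC_011770	XLOC_011770	1.64242	0.964027	0.768677	5.00E-05	0.00453085
XLOC_035762	XLOC_035762	0.522913	0.23768	1.13755	5.00E-05	0.00453085
102191729	LOC102191729	5.17834	2.00733	1.36721	5.00E-05	0.00453085
XLOC_022928	XLOC_022928	0.776793	0.328905	1.23986	5.00E-05	0.00453085
108635658	LOC108635658	439.096	261.643	0.746936	5.00E-05	0.00453085
108637983	LOC108637983	16.501	6.96008	1.24538	5.00E-05	0.00453085
102188339	LOC102188339	170.957	331.264	-0.954346	5.00E-05	0.00453085
108635659	LOC108635659	329.178	167.788	0.972233	5.00E-05	0.00453085
108637984	LOC108637984	12.7238	6.5125	0.966241	5.00E-05	0.00453085
XLOC_011150	XLOC_011150	0	0.388551	NA	5.00E-05	0.00453085
106502102	LOC106502102	1.45025	0.539867	1.42563	5.00E-05	0.00453085
106503367	LOC106503367	2.82561	1.51684	0.897489	5.00E-05	0.00453085
108635656	LOC108635656	647.611	384.805	0.750998	5.00E-05	0.00453085
108636333	LOC108636333	0.393285	0.165964	1.24471	5.00E-05	0.00453085
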