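id	organism	row	distance	identity
1381_Fn	Fervidobacterium nodosum Rt17-B1	TTACG–TAAATCTACCT–GAAAGGACATGTACTT–CAAGGTATTGGGCTGAAC	60	
T12	Caldicellulosiruptor obsidiansis OB47	....AAA.G...AG..A–.....C....CCC...T..G..G....T.A....T	94	67.3
T15	Caldicellulosiruptor saccharolyticus DSM 8903	....AAAG....AG..A– .....C....C.C...T–.G..G....T.A....T	78	67.3
T13	Caldicellulosiruptor kronotskiensis 2002	....AGAG....AG..A–.....C....CCC...–..G..G....T.A....T	94	68.6
T14	Caldicellulosiruptor bescii DSM 6725	....A–AG....AG..A–.....C....TCC...–..G..G....T.A....T	93	70.0
T20	Ammonifex degensii KC4	.....AG.GGC.GC.GG–.....CC..––CT...TT..A.G––....A....A	57	55.7
T19	Thermacetogenium phaeum DSM 12270	.....A.CCCC.GC.GG–.....CC..––CC...T.....G––....A....A	67	59.6
T17	Hydrogenivirga sp. 128-5-R1-1	.....AA...A–....A–––G.ATG..CCCGT..TA..ACG––G.T.A....T	76	42.3
T18D	Desulfurobacterium thermolithotrophum DSM 11699	....AG......–CAGC–..G.AA..TCTGCT..T...A––GCA...A.A..T	55	46.1
T18C	Desulfurobacterium thermolithotrophum DSM 11699	....AGA...C.GTTGC–..G.AAG.CCTGCT..TT..A––GCA...A....T	52	44.2
T18A	Desulfurobacterium thermolithotrophum DSM 11699	....AGA...A..TTGC–..G.AAG.CCTGCT..TT..A––GCA...A.A..T	51	44.2
T18B	Desulfurobacterium thermolithotrophum DSM 11699	....AGA...–..TTGC–..G.AAG.CCTGCT..TT..A––GCA...A.A..T	51	44.2
T6	Thermotoga maritima MSB8	...TCGA.T.AAAC.GCAA.G.A....CCATT..CT.TAAGG.G...A....T	127	43.3
T7A	Thermotoga maritima MSB8	...TCGA.T.AAAC.GCAA.G.A....CCATT..CT.TAAGG.G...A....T	127	43.3
T8A	Thermotoga sp. RQ2	...TCGA.T.AAAC.GCAA.G.A....CCATT..CT.TAAGG.G...A....T	127	43.3
T8B	Thermotoga sp. RQ2	...TCGA.C.AAGT–GCAA.G.A....CCATT..CT.TAAGG.G...A....T	127	41.5
T9A	Thermotoga petrophila RKU-1	...TCGA.C.AAGT–GCAA.G.A....CCATT..CT.TAAGG.G...A....T	127	41.5
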