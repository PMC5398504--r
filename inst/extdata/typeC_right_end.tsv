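id	organism	row	distance	identity
646_Fp	Fervidobacterium pennivorans DSM 9078	–––––––––––––GTTTATTTTTTGTACATTTTTATTTTCGAT–TTTTTGTTCATTTTGA–TATTGACATTTACA–	0	
1012_Fp	Fervidobacterium pennivorans DSM 9078	–––––––––––––..............................–................–..............–	0	100.0
687_Fp	Fervidobacterium pennivorans DSM 9078	–––––––––––––..............................–................–..............–	0	100.0
43_Fi	Fervidobacterium islandicum AW-1	––––CAGAAATTTTGCGTCC.GG.T..TGC.G..G.GC.TT..–....–...–....AT.T....–T.–.AG–..–	nd	50.8
T1	Caldicellulosiruptor lactoaceticus 6A	–––––––––––––..............................–................–..............–	0	100.0
T2	Caldicellulosiruptor lactoaceticus 6A	–––––––––––––..............................–................–..............–	0	100.0
T3	Caldicellulosiruptor lactoaceticus 6A	–––––––––––––..............................–................–..............–	0	100.0
T7	Thermoanaerobacter matharanii A3	–––––––––––––..AC............AAA....A...C.C–.......A..AAAAT.–.......T......G	nd	73.7
T6	Clostridium ultunense Esp	––––––––––––––––––––..........AA........C.C–......A.....C.T.–.............––	nd	86.5
T12B	Kosmotoga olearia TBF 19.5.1	ACTACGCAAATCT.A.CGA.GAAAC...GCAA..T.G......G.....A.G.T....TG––G.C..TG..G...–	nd	55.7
T12A	Kosmotoga olearia TBF 19.5.1	ACTACGCAAATCT.AGCGA.GAAAT...GCAA..T.GA.....G.....T.G......TG––G....TG..G...–	nd	55.7
T12C	Kosmotoga olearia TBF 19.5.1	ACTACGCAAATCT.A.CGA.GAAAC...GCAA..T.G......G.....A.G.T....TG––G.C..TG..G...–	nd	55.7
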