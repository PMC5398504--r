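id	organism	row	distance	identity
646_Fp	Fervidobacterium pennivorans DSM 9078	–––––––TGTTAATGATAAAATA–––AAAATGT–ACTGAAAGTGGAATATAAGGATGTACAAAAT–TGTAC–––	41	
1012_Fp	Fervidobacterium pennivorans DSM 9078	–––––––................–––.......–...............................–.....–––	41	100.0
687_Fp	Fervidobacterium pennivorans DSM 9078	–––––––................–––.......–...............................–.....–––	41	100.0
43_Fi	Fervidobacterium islandicum AW-1	–––––––................–––.......–...............................–.....–––	41	100.0
T1	Caldicellulosiruptor lactoaceticus 6A	–––––––................–––.......–...............................–.....–––	41	100.0
T2	Caldicellulosiruptor lactoaceticus 6A	–––––––G...............–––.......–..................T............–.....–––	41	96.6
T3	Caldicellulosiruptor lactoaceticus 6A	–––––––....G...........–––.......–...................A...........–.....–––	41	96.6
T7	Thermoanaerobacter matharanii A3	––––––C...A...A........–––.G.....–..GA.........A....AA.......G.T.–.....–––	82	81.7
T6	Clostridium ultunense Esp	––––––––..A...........T–––.G.....–..AATT.A.....A.....A..........G–..––––––	36	80.3
T12B	Kosmotoga olearia TBF 19.5.1	GTGTCGACA.CG..T........GTA....C..CGG.C...AAT..GC.A..AC..CGGT..G.AT..AGTAGT	38	42.4
T12A	Kosmotoga olearia TBF 19.5.1	GTGTCGACA.CG..T........GTA....C..CGG.C...AAT..GC.A..AC..CGGT..G.AT..AGTAGT	38	42.4
T12C	Kosmotoga olearia TBF 19.5.1	GTGTCGACA.CG..T........GTA....C..CGG.C...AAT..GC.A..AC..CGGT..G.AT..AGTAGT	38	42.4
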