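id	organism	row	distance	identity
10_Ft	Fervidobacterium sp. FC2004	GGGAGTACAATAAATTTTGTGTCTGGAAAATTTTAGCTTGCTAA	40	
11_Ft	Fervidobacterium sp. FC2004	...............................C............	40	97.7
29_Ft	Fervidobacterium sp. FC2004	..........G.................................	40	97.7
3_Ft	Fervidobacterium sp. FC2004	............................................	40	100.0
T5B	Caldicellulosiruptor lactoaceticus 6A	...T..TA..AT..AA.........A.GT..GA..AAA.CGC..	15	59.0
T4C	Caldicellulosiruptor kristjanssonii I77R1B	...T..TA..AT..AA.........A.GT..GA..AAA.CGC..	15	59.0
T4B	Caldicellulosiruptor kristjanssonii I77R1B	...T..TA..AT..AA.........A.GT..GA..AAA.CGC..	15	59.0
T9A	Caldicellulosiruptor owensensis OL	...T..TA..AT..AG.........AT.T..AA..AAA.CAC..	50	59.0
T9B	Caldicellulosiruptor owensensis OL	...T..TA..AT..AG.........AT.T..AA..AAA.CAC..	51	59.0
T20	Caldanaerobacter subterraneus DSM 12653	..AT..TA..AT..AA.........ATGT..AA.GAAA.TG...	332	54.5
T19	Thermoanaerobacter sp. X514	..AT..TA..AT..AA.........ATGT..AA.GAAA.TG...	333	54.5
T7A	Clostridium stercorarium DSM 8532	...T..TA..AT..AA..........TGT..AA..AAA.CAC..	15	59.0
T7B	Clostridium stercorarium DSM 8532	...T..TA..AT..AA..........TGT..AA..AAA.CAC..	15	59.0
T6A	Caldicellulosiruptor saccharolyticus DSM 8903	......TA..AT..AA.......CACTGT..AA.TAG.GTTG..	27	52.2
T6B	Caldicellulosiruptor saccharolyticus DSM 8903	......TA..AT..AA.......CACTGT..AA.TAG.GTTG..	27	52.2
T6C	Caldicellulosiruptor saccharolyticus DSM 8903	.AA...TA..AT..AA.......CATTGT.GAA.TAG.ATTG..	78	45.4
T5A	Caldicellulosiruptor lactoaceticus 6A	......TA..AT..AA.......CACTGT..AA.TAG.ATTG..	26	52.2
T4A	Caldicellulosiruptor kristjanssonii I77R1B	......TA..AT..AA.......CACTGT..AA.TAG.ATTG..	26	52.2
T5C	Caldicellulosiruptor lactoaceticus 6A	......TA..AT..AA........ACTGT..AA.TAG.ATTG.G	25	52.2
T1	Caldicellulosiruptor obsidiansis OB47	......TA..AT..AA.......CACTGT..AA.TAG.ATTG..	26	52.2
T3	Caldicellulosiruptor bescii DSM 6725	......TA..AT..AA.......CACTGT..AA.TAG.ATTG..	26	52.2
T2A	Thermoanaerobacter italicus Ab9	......TA..AT..AA.......CACTGT..AA.TAGAATTG..	26	50.0
T2B	Thermoanaerobacter italicus Ab9	......TA..AT..AA.......CACTGT..AA.TAGAATTG..	26	50.0
T12	Thermotoga thermarum DSM 5069	......T.G.AT..............TGGTAAGATTA...TAC.	17	59.0
T17	Hydrogenobaculum sp. SN	......TA..AT.T..A.......TA..CT.AAACA...TA.C.	20	59.0
T10	Sulfurihydrogenibium sp. YO3AOP1	......TA..AT...G........AA.TT.AA..TATAA.GAGG	7	54.5
T23	Hippea maritima DSM 10411	....C.TA..AT.T..........CCCCC.CAAACCTACTAA..	69	47.7
T18	Thermodesulfatator indicus DSM 15286	.A.G.CGGG.A...........AA..GT..AA..TAAGAAACTC	19	47.7
T25	Sulfolobus islandicus M.14.25	.AAGC.CGGGGCT.CCAGT.A.AGTTGTGG.AG.CAAAG.TG..	5	22.7
T13A	Kosmotoga olearia TBF 19.5	...TC.GTT.GC..........AAACTCCC.CCG.AA.ATGAG.	29	43.1
T13B	Kosmotoga olearia TBF 19.5	...TC.GTT.GT..........AAACTCCC.CCG.AA.ATGAG.	29	43.1
T15A	Mesotoga prima MesG1.Ag.4.2	.A.TA.GT..AG..GA......AAACCCTC.AGA.TGGAAGAG.	19	36.3
T15B	Mesotoga prima MesG1.Ag.4.2	.A.TA.GT..AG..GA......AAACCCTC.AGA.TGGAAGAG.	19	36.3
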