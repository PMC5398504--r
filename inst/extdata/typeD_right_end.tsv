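id	organism	row	distance	identity
10_Ft	Fervidobacterium sp. FC2004	GTGTTTGTTCTCTTTTCTTCGGACACAAAATTCTTGGACA–GTCTC	71	
11_Ft	Fervidobacterium sp. FC2004	...G.................................T..–.....	70	95.5
29_Ft	Fervidobacterium sp. FC2004	...G.................................T..–.....	nd	95.5
3_Ft	Fervidobacterium sp. FC2004	...G...............A....................–.....	71	95.5
T5B	Caldicellulosiruptor lactoaceticus 6A	CA...ACGCTA.–...ACC.A...............–...A.....	-33	67.3
T4C	Caldicellulosiruptor kristjanssonii I77R1B	CA...ACGCTA.–...ACC.A...............–...A.....	-33	67.3
T4B	Caldicellulosiruptor kristjanssonii I77R1B	CA...ACGCTA.–...ACC.A...............–...A.....	-33	67.3
T9A	Caldicellulosiruptor owensensis OL	CA...ACGCTA.–...ACC.A...............–...A.....	-33	67.3
T9B	Caldicellulosiruptor owensensis OL	CA...ACGCTA.–...ACC.A...............–...A.....	-33	67.3
T20	Caldanaerobacter subterraneus DSM 12653	CA...ACG.TA.–...AAC.A...............–...A.....	-33	69.5
T19	Thermoanaerobacter sp. X514	CA...ACG.TA.–...AAC.A...............–...A.....	-33	69.5
T7A	Clostridium stercorarium DSM 8532	CA...ACG.TA.–...AA..A...............–...AC....	-33	69.5
T7B	Clostridium stercorarium DSM 8532	CA...ACG.TA.–...AA..A...............–...AC....	16	69.5
T6A	Caldicellulosiruptor saccharolyticus DSM 8903	AATA.ACGCTAT–GAAA.GGAA..............–...A.....	-33	52.1
T6B	Caldicellulosiruptor saccharolyticus DSM 8903	AATA.ACGCTAT–GAAA.GGAA..............–...A.....	-33	52.1
T6C	Caldicellulosiruptor saccharolyticus DSM 8903	AATA.ACGCTAT.GA.G.GGAA..............–...A.....	-12	56.5
T5A	Caldicellulosiruptor lactoaceticus 6A	AATA.GCGCTAT–GAAA.GGAA..............–...A.....	-33	52.1
T4A	Caldicellulosiruptor kristjanssonii I77R1B	AATA.GCGCTAT–GAAA.GGAA..............–...A.....	-33	52.1
T5C	Caldicellulosiruptor lactoaceticus 6A	AAC..ACG.TAT–AAAT.GGAA..............–...A.....	-33	56.5
T1	Caldicellulosiruptor obsidiansis OB47	AAT..ACG.TAT–AAAT.GGAA..............–...A.....	-33	56.5
T3	Caldicellulosiruptor bescii DSM 6725	AAC..GCG.TAT–AAAT.GGAA..............–...A.....	-33	56.5
T2A	Thermoanaerobacter italicus Ab9	AAC..ACG.TAT–AAGT.GGAA..............–...A.....	-33	56.5
T2B	Thermoanaerobacter italicus Ab9	AAC..ACG.TAT–AAGT.GGAA..............–...A.....	-33	56.5
T12	Thermotoga thermarum DSM 5069	AAC.G–AGGTAT–...G.C.A............ACC–CT.A.....	-35	52.1
T17	Hydrogenobaculum sp. SN	AACAGGAGAT.T–.G.TA.GA...........A...–...A.....	-33	56.5
T10	Sulfurihydrogenibium sp. YO3AOP1	AATAAAAAGT.T–.CAA.C.A...........A...–.T.A.....	-33	54.3
T23	Hippea maritima DSM 10411	––––..TGGTATGA.GAGAGA.........A.TAG.–GG.T.....	7	43.4
T18	Thermodesulfatator indicus DSM 15286	AACAGGT.ATCAGC.AACCTTT..........TC.T–.T.G.C...	4	41.3
T25	Sulfolobus islandicus M.14.25	––––––––.TA.A.A.T...TT......CTA.ACCC–.GTA.C.C.	8	39.1
T13A	Kosmotoga olearia TBF 19.5	TCT...CCGGAG...GGGGTTT.........ATG..–...C.C.CG	nd	47.8
T13B	Kosmotoga olearia TBF 19.5	TCT...CCGGAG...GGAGTTT.........ATG..–...T.C.CG	nd	47.8
T15A	Mesotoga prima MesG1.Ag.4.2	ACCCA.TACAAAAAAGGGGTTT........AA–GA.–...GAA.C–	7	30.4
T15B	Mesotoga prima MesG1.Ag.4.2	ACCCA.TACAAAAAAGGGGTTT........AAAGA.–...GAA.C–	7	30.4
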