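id	organism	row	distance	identity
243_Fn	Fervidobacterium nodosum Rt17-B1	GGCTCTAT–AA–––T–AAATA–––TTGGGGTGGGTA–AA––AAG–GA–––––AAAAA–––––––TATAGCACTTATTCTGAATGCC	65	
343_Fn	Fervidobacterium nodosum Rt17-B1	........–..–––.–.....–––............–..––...–..–––––.....–––––––......................	65	100.0
999_Fn	Fervidobacterium nodosum Rt17-B1	........–..–––.–.....–––............–..––...–..–––––.....–––––––......................	65	100.0
1160_Fn	Fervidobacterium nodosum Rt17-B1	........–..–––.–.....–––............–..––...–..–––––.....–––––––......................	65	100.0
1322_Fn	Fervidobacterium nodosum Rt17-B1	........–..–––.–.....–––............–..––...–..–––––.....––––––––......................	65	100.0
1405_Fn	Fervidobacterium nodosum Rt17-B1	........–..–––.–.....–––........T...–..––...–..––––––.....–––––––......................	65	98.3
1408_Fn	Fervidobacterium nodosum Rt17-B1	........–..–––.–.....–––............–..––...–..–––––.....–––––––......................	65	100.0
1532_Fn	Fervidobacterium nodosum Rt17-B1	........–..–––.–.....–––............–..––...–..–––––.....–––––––......................	65	100.0
T2	Caldicellulosiruptor owensensis OL	........–..–––.–.....–––.........A..G.TAG––.–..–––––.....–––––––......................	64	89.2
T1A	Caldicellulosiruptor kronotskiensis 2002	........–..–––.–.....–––.........–..–.––G..AA..–––––.....–––––––......................	65	92.1
T1B	Caldicellulosiruptor kronotskiensis 2002	........–..–––.–.....–––.........–..–.––G..AA..–––––.....–––––––......................	66	92.1
T1C	Caldicellulosiruptor kronotskiensis 2002	........–..–––.–.....–––.........–..–.––G..AA..–––––.....–––––––......................	65	92.1
T3	Caldanaerobacter subterraneus subsp. yonseiensis KB-1	..T.....–..–––.–....–––G..........G.A..AG..–ATCT–ATA.....–––––––G.G...................	53	76.0
T4	Caldanaerobacter subterraneus subsp. pacificus DSM 12653	..T.....–..–––.–....–––G..........G.A..AG..–ATCT–ATA.....–––––––G.G...................	53	76.0
T7	Thermoanaerobacter wiegelii Rt8.B1	..T.....–..–––.–....–––G........AA..A..AG––.ATC–––TA.....–––––––C.G...................	49	75.3
T5A	Thermoanaerobacter pseudethanolicus ATCC 33223	..T.....–..–––.–....–––G..........G.A..AG..–ATCT–AT–.....–––––––G.G...................	52	77.1
T6	Thermoanaerobacter ethanolicus JW200	..T.....–..–––.–....–––G........TAGGGG.–G..AA..––AT–.....–––––––..G...................	50	77.9
T10	Thermoanaerobacter ethanolicus CCSD1	..T.....–..–––.–....–––G..........G.A..AG..–ATCT–ATA.....–––––––G.G...................	52	76.0
T5B	Thermoanaerobacter pseudethanolicus ATCC 33223	..T.....–..–––.–....–––G..........G.A..AG..–ATCT–ATA.....–––––––G.G...................	52	76.0
T13B	Petrotoga mobilis SJ95	.....–––G..T––.C..–.–––––.–––––––––––––––..––TC––A––––––––––––––CTGC.–.–..–..–––––...A	273	34.8
T13C	Petrotoga mobilis SJ95	...–.–T.G..AGG.C..–.–––––C–––––––––––––––...–T–––AT–––––––––––––C–G–.–.–.––..––––...GG	nd	31.8
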