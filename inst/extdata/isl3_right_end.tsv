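id	organism	row	distance	identity
243_Fn	Fervidobacterium nodosum Rt17-B1	GGCATTCAGAA–––––––––TA––––––––––––––––––––––––––––––CCCACCCCA–C––TACTTGA–––––CAAAGAGCC	129	
343_Fn	Fervidobacterium nodosum Rt17-B1	...........–––––––––..––––––––––––––––––––––––––––––.........–.––.......–––––.........	129	100.0
999_Fn	Fervidobacterium nodosum Rt17-B1	...........–––––––––..––––––––––––––––––––––––––––––.........–.––.......–––––.........	129	100.0
1160_Fn	Fervidobacterium nodosum Rt17-B1	...........–––––––––..––––––––––––––––––––––––––––––.........–.––.......–––––.........	129	100.0
1322_Fn	Fervidobacterium nodosum Rt17-B1	...........–––––––––..––––––––––––––––––––––––––––––.........–.––.......–––––.........	129	100.0
1405_Fn	Fervidobacterium nodosum Rt17-B1	...........–––––––––..––––––––––––––––––––––––––––––.........–.––.......–––––.........	129	100.0
1408_Fn	Fervidobacterium nodosum Rt17-B1	...........–––––––––..––––––––––––––––––––––––––––––.........–.––.......–––––.........	129	100.0
1532_Fn	Fervidobacterium nodosum Rt17-B1	...........–––––––––..––––––––––––––––––––––––––––––.........–.––.......–––––.........	129	100.0
T2	Caldicellulosiruptor owensensis OL	...........–––––––––..––––––––––––––––––––––––––––––.........A.––.–.....–––––......A..	126	92.5
T1A	Caldicellulosiruptor kronotskiensis 2002	..........G–––––––––..––––––––––––––––––––––––––––––.........A.––.–.....–––––.........	128	92.5
T1B	Caldicellulosiruptor kronotskiensis 2002	..........G–––––––––..––––––––––––––––––––––––––––––.........A.––.–.....–––––.........	128	92.5
T1C	Caldicellulosiruptor kronotskiensis 2002	...........–––––––––..––––––––––––––––––––––––––––––T........A.––.–.....–––––.........	128	92.5
T3	Caldanaerobacter subterraneus subsp. yonseiensis KB-1	...........AAA–––––A..––––––––––––––––––––––––––––––.........A.––..–....–––––.........	nd	86.3
T4	Caldanaerobacter subterraneus subsp. pacificus DSM 12653	...........AAA–––––A..––––––––––––––––––––––––––––––.........A.––..–....–––––.........	nd	86.3
T7	Thermoanaerobacter wiegelii Rt8.B1	...........AAA–––––A..––––––––––––––––––––––––––––––.........A.––..–....–––––.........	152	86.3
T5A	Thermoanaerobacter pseudethanolicus ATCC 33223	...........AAA–––––A..––––––––––––––––––––––––––––––.........A.––..–....–––––.........	164	86.3
T6	Thermoanaerobacter ethanolicus JW200	...........AAAA––––A..––––––––––––––––––––––––––––––.........A.––..–....–––––......A..	153	82.2
T13B	Petrotoga mobilis SJ95	AA..–––––..AAA–T–CGC.GTATTACCTTTTTCATCATCTCTTC–AGTCTATTCTAT..A.CA..T....–––––.........	8	29.4
T13C	Petrotoga mobilis SJ95	AA..–––––..AAA–T–CTC.GTAATACCTTTTTCATCATCTCTTC–AGTCTATTCT–T..A.CA..T....–––––...G.....	8	29.4
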