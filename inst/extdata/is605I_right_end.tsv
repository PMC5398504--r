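id	organism	row	distance	identity
1381_Fn	Fervidobacterium nodosum Rt17-B1	AGCA–GGAAGCCAAT–CCCTTA–A–AAG–GGG––TAGGAGGAGGTCAA	0	
T12	Caldicellulosiruptor obsidiansis OB47	.––––....T..T..C.....C––––..–...AT.G............	22	72.7
T15	Caldicellulosiruptor saccharolyticus DSM 8903	.CATG....T..T..C.....C––––..–...AT.G............	85	71.1
T13	Caldicellulosiruptor kronotskiensis 2002	..A––....T..T..C.....C––––..–...AT.G............	22	75.0
T14	Caldicellulosiruptor bescii DSM 6725	..A––....T..T..C.....C––..–...AT.G............	22	75.0
T20	Ammonifex degensii KC4	..G––.......C.C–..T..C––––.A–...––.G...........C	1	73.1
T19	Thermacetogenium phaeum DSM 12270	..A––.......C.C–.....T––––..–...––.G...........C	1	78.0
T17	Hydrogenivirga sp. 128-5-R1-1	....–......TCGGCTT...T––––.A–A.C––CGA.....T....C	-21	57.1
T18D	Desulfurobacterium thermolithotrophum DSM 11699	....–.......T.C–.A..–––.–...–T..––........T....C	-26	80.4
T18C	Desulfurobacterium thermolithotrophum DSM 11699	....–.......CC.–.A...T––––..–T.A––GG......T....C	-20	70.7
T18A	Desulfurobacterium thermolithotrophum DSM 11699	....–.......C.C–.A...T––––..–T..––.G......T....C	0	75.6
T18B	Desulfurobacterium thermolithotrophum DSM 11699	....–.......T.C–.A...T––––..–T..––........T....C	-20	78.0
T6	Thermotoga maritima MSB8	...G–.......–..–GA...CT.T...–TCA––.G.T..––T–...C	0	60.4
T7A	Thermotoga maritima MSB8	...G–.......–..–GA... CT.T...–TCA––.G.T..––T–...C	0	60.4
T8A	Thermotoga sp. RQ2	...G–.......–..–GA...CT.T...–TCA––.G.T..––T–...C	0	60.4
T8B	Thermotoga sp. RQ2	...G–....A..–.C–AT...CTGT...GT..–––G.T..––T–...C	0	54.5
T9A	Thermotoga petrophila RKU-1	...G–.......–.C–AT...CTGT...GT..–––G.T..––T–...C	0	56.8
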