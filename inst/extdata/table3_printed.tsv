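species	level	genomes	B1	B2	B3	B5	B6	B7	B9	B12	abundance_pct
Bacteroides thetaiotaomicron	S	3	1	1	1	1	1	1	1	0	25.5
Escherichia fergusonii	S	5	1	1	1	1	1	1	1	0	21.0
Flavonifractor plautii	S	3	0	0	0	0	0	0	0	1	6.9
Peptoniphilus grossensis	S	2	0	1	0.5	0	0	0	1	0	6.7
Finegoldia magna	S	6	1	0	0	0	1	0	1	0	5.0
Bacteroides faecis	S	2	1	1	1	1	1	1	1	0	4.5
Bacteroides vulgatus	S	6	1	1	1	1	1	1	1	1	3.1
Bacteroides caccae	S	3	1	1	1	1	1	1	1	0	3.1
Clostridium perfringens	S	4	1	1	1	0	0	0	1	1	2.5
Phascolarctobacterium faecium	G	1	1	1	0	1	1	1	1	1	1.8
Bacteroides massiliensis	S	1	1	1	1	1	1	1	1	0	1.7
Bacteroides uniformis	S	7	1	1	1	1	1	1	1	1	1.7
Agathobaculum desmolans	S	1	0	0	0	0	0	0	0	1	1.2
Akkermansia muciniphila	S	4	1	1	1	1	1	1	1	0.25	1.2
Pseudoflavonifractor phocaeensis	G	3	0	0.5	0	0	0	0	0	0.5	1.2
Bacteroides ovatus	S	7	1	1	1	1	1	1	1	0	1.0
Parabacteroides merdae	S	4	1	1	1	1	1	1	1	1	0.9
Eggerthella lenta	S	3	1	0	0	0.67	1	0	1	0	0.6
Flintibacter butyricus	S	3	0	0	0	0	0	0	0	1	0.2
Pseudoflavonifractor capillosus	S	1	0	0	0	0	0	0	0	1	0.2
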