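species	level	genomes	B1	B2	B3	B5	B6	B7	B9	B12	abundance_pct
Akkermansia muciniphila	S	4	1	1	1	1	1	1	1	0.25	26.3
Muribaculum intestinale	S	1	1	1	1	1	1	1	1	0	10.2
Faecalibacterium prausnitzii	S	6	0	0.67	0	0	1	0	0	1	9.8
Bacteroides xylanisolvens	S	4	1	1	1	1	1	1	1	0.25	4.5
Blautia glucerasea	S	1	1	0	1	0	1	0	1	1	3.6
Parabacteroides distasonis	S	4	1	1	1	1	1	1	1	1	3.1
Murimonas intestini	F	224	0.48	0.56	0.7	0.25	1	0.15	0.49	0.81	3.0
Phascolarctobacterium faecium	G	1	1	1	0	1	1	1	1	1	2.5
Bacteroides fragilis	S	6	1	1	1	1	1	1	1	1	2.3
Bacteroides uniformis	S	7	1	1	1	1	1	1	1	1	2.2
Bacteroides vulgatus	S	6	1	1	1	1	1	1	1	1	2.0
Coprococcus eutactus	S	1	1	1	1	1	1	0	1	0	1.6
Sutterella massiliensis	G	4	0	1	0	0	1	0.5	1	0	1.6
[Eubacterium] rectale	S	3	1	1	1	1	1	0	0	1	1.4
Bacteroides stercoris	S	2	1	1	1	1	1	1	1	1	1.2
Blautia faecis	G	23	0.75	0.31	0.77	0.07	1	0.19	0.86	1	1.1
Bacteroides stercorirosoris	S	1	1	1	1	1	1	1	1	0	0.9
Bacteroides cellulosilyticus	S	3	1	1	1	1	1	1	1	1	0.8
Ruminococcus champanellensis	S	2	0	0	1	0	1	0	1	0	0.8
Parabacteroides goldsteinii	S	3	1	1	1	1	1	1	1	1	0.8
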