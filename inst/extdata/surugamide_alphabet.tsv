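position	aa	normalized_score
1	val	100
1	ile	80
1	abu	70
2	phe	100
2	tyr	90
2	bht	90
2	val	75
3	tyr	100
3	phe	100
3	leu	100
3	arg	86
3	cys	75
4	val	100
4	ile	100
4	abu	70
5	ala	100
5	ser	87
5	pro	75
5	phe	75
5	gly	75
6	val	100
6	ile	100
6	abu	70
7	val	100
7	ile	100
7	abu	70
8	met	100
8	apa	100
8	glu	86
8	gln	86
8	lys	86
8	asp	86
8	val	86
8	orn	86
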