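name	monoisotopic_mass_Da
gly	57.02146
ala	71.03711
ser	87.03203
pro	97.05276
val	99.06841
thr	101.04768
cys	103.00919
leu	113.08406
ile	113.08406
asn	114.04293
asp	115.02694
gln	128.05858
lys	128.09496
glu	129.04259
met	131.04049
his	137.05891
phe	147.06841
arg	156.10111
tyr	163.06333
trp	186.07931
abu	85.05276
orn	114.07931
dab	100.06366
bht	179.05824
apa	99.06841
hyv	115.06333
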