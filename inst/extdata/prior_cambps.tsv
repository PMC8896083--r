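protein	note
BACE1	beta-secretase 1
BIN1	bridging integrator 1
CaMKII	Ca2+/CaM-dependent protein kinase II
PP2B	calcineurin (protein phosphatase 2B)
PMCA	plasma-membrane Ca2+ ATPase
NOS	nitric oxide synthase
NMDAR	N-methyl-D-aspartate receptor
AchR	acetylcholine receptor
Ado A2AR	adenosine A2A receptor
Abeta	amyloid beta
APOE	apolipoprotein E
SNCA	alpha-synuclein
TMEM175	transmembrane protein 175
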