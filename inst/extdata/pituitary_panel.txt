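# Pituitary-development gene panel.
# INCOMPLETE: partial reconstruction (26 genes) of the 42-gene panel used
# in the motivating congenital-hypopituitarism trio study; only the genes
# individually named in the published report are listed. Supply the full
# panel file for faithful reproduction.
HESX1
SOX2
SOX3
TBX2
TBX3
LHX2
LHX3
LHX4
SIX1
SIX3
SIX5
SIX6
PITX1
PITX2
PROP1
POU1F1
TBX19
ARID1B
CDON
CHD7
GLI1
GLI4
PAX6
WNT5A
PROKR2
WDR11
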