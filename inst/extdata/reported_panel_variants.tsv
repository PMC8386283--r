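group	subject	gene	variant	type	inherited_from	gnomad_af
case	HP1	CDON	chr11:125887183_C>T	missense	mother	NA
case	HP1	ARID1B	chr6:157454234_C>T	missense	mother	0.004
case	HP2	SIX6	chr14:60976501_G>A	missense	mother	0.007
case	HP3	SIX1	chr14:61113110_G>A	missense	mother	0.003
case	HP4	LHX4	chr1:180235637_G>A	missense	father	NA
case	HP4	CDON	chr11:125859642_C>T	nonsense	father	0.00006
case	HP4	SIX5	chr19:46268833_C>T	missense	mother	0.0002
case	HP5	ARID1B	chr6:157522148_C>A	missense	mother	0.00001
case	HP6	GLI1	chr12:57865830_AA>A	frameshift	mother	0.000006
case	HP6	SOX3	chrX:139586486_CAGCGGCGGCGGCCGCGGCAGC>C	inframe_indel	father	NA
case	HP6	CHD7	chr8:61693942_61693947insGCAAAA	inframe_indel	mother	NA
case	HP7	GLI4	chr8:144358408_G>C	missense	father	0.0001
case	HP8	LHX3	chr9:139091601_G>T	missense	father	0.0002
control	NFSS1	CHD7	chr8:61774876_A>G	missense	father	0.00001
control	NFSS2	LHX4	chr1:180243593_C>T	missense	mother	0.0002
control	NFSS3	LHX4	chr1:180217489_A>G	missense	mother	0.0001
control	NFSS4	WNT5A	chr3:55508427_T>C	missense	mother	0.00001
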