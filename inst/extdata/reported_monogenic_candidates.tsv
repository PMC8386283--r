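group	trio	mode	gene	causative
case	HP01	de_novo	TTLL4	FALSE
case	HP01	AR_compound_het	TNXB	FALSE
case	HP02	de_novo	KLHDC4	FALSE
case	HP03	de_novo	MARCH3	FALSE
case	HP03	AR_compound_het	PER2	FALSE
case	HP03	AR_compound_het	FLG	FALSE
case	HP04	de_novo	CRHR1	FALSE
case	HP04	XLR	GPC3	FALSE
case	HP05	AR_homozygous	TTLL6	FALSE
case	HP05	AR_homozygous	DCAKD	FALSE
case	HP08	AR_compound_het	PDE4DIP	FALSE
case	HP09	AR_compound_het	CEP128	FALSE
case	HP10	AR_homozygous	MET	FALSE
case	HP11	AR_homozygous	PRRG2	FALSE
case	HP12	de_novo	GJB5	FALSE
case	HP12	AR_homozygous	ACADVL	FALSE
case	HP12	AR_compound_het	RGPD3	FALSE
control	NF01	de_novo	SMARCD2	FALSE
control	NF01	AR_compound_het	TMBIM1	FALSE
control	NF02	AR_homozygous	APLP2	FALSE
control	NF02	AR_compound_het	ZFHX3	FALSE
control	NF03	AR_compound_het	BRF1	TRUE
control	NF03	AR_compound_het	MCM3AP	FALSE
control	NF04	AR_compound_het	SDSL	FALSE
control	NF05	AR_compound_het	FZD6	FALSE
control	NF05	AR_compound_het	HECW2	FALSE
control	NF05	AR_compound_het	WDR52	FALSE
control	NF06	de_novo	QRICH1	TRUE
control	NF06	AR_homozygous	PQLC2	FALSE
control	NF07	de_novo	FBXO41	FALSE
control	NF07	AR_compound_het	PEX6	FALSE
control	NF08	de_novo	PDCD6IP	FALSE
control	NF08	AR_compound_het	SRRM2	FALSE
control	NF09	de_novo	FBN1	TRUE
control	NF10	de_novo	ZNF506	FALSE
control	NF10	XLR	HUWE1	TRUE
control	NF11	de_novo	SRCAP	TRUE
control	NF12	AR_homozygous	MMP8	FALSE
control	NF12	AR_homozygous	SPTB	FALSE
control	NF13	AR_homozygous	DDX46	FALSE
control	NF13	AR_homozygous	MRGPRX1	FALSE
control	NF13	AR_compound_het	FTCD	FALSE
control	NF13	AR_compound_het	MCOLN3	FALSE
control	NF13	AR_compound_het	RYR1	FALSE
control	NF13	AR_compound_het	MLH1	FALSE
control	NF14	de_novo	ACAN	TRUE
control	NF14	XLR	BCOR	FALSE
control	NF14	XLR	NAP1L2	FALSE
control	NF14	XLR	ACTRT1	FALSE
control	NF14	XLR	MAGEC2	FALSE
control	NF15	de_novo	ZEB2	TRUE
control	NF15	XLR	COL4A5	FALSE
control	NF17	AR_compound_het	CYFIP2	FALSE
control	NF17	AR_compound_het	IL7R	FALSE
control	NF17	AR_compound_het	NRAP	FALSE
control	NF18	AR_homozygous	LRP1B	FALSE
control	NF19	AR_compound_het	PLBD1	FALSE
control	NF19	AR_compound_het	HEG1	FALSE
control	NF19	AR_compound_het	CUL7	TRUE
control	NF19	XLR	APOOL	FALSE
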