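CBC	synthetic example: crypt-base columnar marker set	LGR5	ASCL2	OLFM4	SMOC2	RGMB	SLC12A2
RSC	synthetic example: regenerative stem cell marker set	ANXA1	CLU	PLAUR	TACSTD2	EMP1	LAMC2
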