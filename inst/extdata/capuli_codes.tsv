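# Composed digestion patterns identifying capuli S-RNase alleles
# (letters refer to the RsaI, MboI and HinfI patterns, in that order)
allele	code
S_1	PJN
S_3	BEJ
S_4	OLI
S_5	DFC
S_6	CIE
S_7	EGL
S_8	LHQ
S_9	IMK
S_10	KNJ
S_12	JFF
S_13	HCP
S_14	GBM
S_15	FCA
S_16	MKG
S_17	FCE
S_18	NOO
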